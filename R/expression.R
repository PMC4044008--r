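#' RPKM expression level
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `1e9 * count / (total_mapped * length_nt)`.  Linear in `count`,
#' inverse-linear in transcript length and library size.
#'
#' @param count Read count(s), non-negative.
#' @param length_nt Transcript length(s) in nucleotides, positive.
#' @param total_mapped Total mapped reads in the library, positive.
#' @return Numeric RPKM value(s).
#' @export
#' @examples
#' compute_rpkm(10, 1000, 1e6)  # 10
compute_rpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("length_nt must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  ## double arithmetic: integer library sizes times lengths overflow int32
  1e9 * as.numeric(count) / (as.numeric(total_mapped) * as.numeric(length_nt))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: for the i-th smallest p-value,
#' `adj_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, returned in the
#' original input order.  Delegates to [stats::p.adjust()] after input
#' validation.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of FDR-adjusted values, same order as input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

## Default per-transcript count test: a two-sided exact binomial test of
## the pooled treatment count against the expectation under equal
## (library-size-proportional) expression.  Appropriate for pooled counts
## when no replicate dispersion model is assumed.
binomial_count_test <- function(control, treatment, total_control, total_treatment) {
  p0 <- total_treatment / (total_control + total_treatment)
  vapply(seq_along(control), function(i) {
    n <- control[i] + treatment[i]
    if (n == 0L) return(1)
    stats::binom.test(treatment[i], n, p = p0)$p.value
  }, numeric(1L))
}

#' Differential-expression screen
#'
#' Quantifies each transcript as RPKM in control and treatment, computes
#' the fold change on pseudocounted RPKM (one read added to each
#' condition's pooled count, so condition-specific transcripts with a
#' zero count do not divide by zero), tests each transcript with a
#' pluggable count test (default: two-sided binomial test of pooled
#' counts against library-size proportions), adjusts p-values with
#' Benjamini-Hochberg across all transcripts, and calls the direction:
#' `up` iff `fold_change >= fold_threshold` and `fdr < fdr_threshold`;
#' `down` iff `fold_change <= 1/fold_threshold` and `fdr < fdr_threshold`;
#' otherwise `unchanged`.  Both gates are required: a large fold change
#' with a weak FDR stays `unchanged`.
#'
#' @param counts A `count_table` object (see [read_counts()]), or a list
#'   with elements `ids`, `control`, `treatment` (matrices, rows =
#'   transcripts, columns = replicates).  Replicates are summed to pooled
#'   counts for the default test.
#' @param lengths_nt Named vector of transcript lengths (nt); must cover
#'   every id in `counts`.
#' @param fold_threshold Fold-change gate (default 2).
#' @param fdr_threshold FDR gate (default 0.001).
#' @param total_control,total_treatment Library sizes (total mapped reads)
#'   per condition; default: column-sum totals of the pooled counts.
#' @param pseudocount Reads added to each condition's pooled count before
#'   the fold-change ratio (default 1).
#' @param test_fun Optional replacement count test: a
#'   `function(control, treatment, total_control, total_treatment)`
#'   receiving pooled count vectors and returning a p-value vector.
#' @return Data frame with columns `id`, `rpkm_control`, `rpkm_treatment`,
#'   `fold_change`, `p_value`, `fdr`, `direction`.
#' @export
call_differential <- function(counts, lengths_nt,
                              fold_threshold = 2, fdr_threshold = 0.001,
                              total_control = NULL, total_treatment = NULL,
                              pseudocount = 1, test_fun = NULL) {
  if (!all(c("ids", "control", "treatment") %in% names(counts))) {
    stop("'counts' must have ids, control and treatment components")
  }
  ids <- counts$ids
  if (length(ids) == 0L) {
    return(data.frame(id = character(), rpkm_control = numeric(),
                      rpkm_treatment = numeric(), fold_change = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  missing_len <- setdiff(ids, names(lengths_nt))
  if (length(missing_len)) {
    stop("missing transcript length(s) for: ",
         paste(utils::head(missing_len, 5L), collapse = ", "))
  }
  len <- as.numeric(lengths_nt[ids])
  cc <- rowSums(counts$control)
  tc <- rowSums(counts$treatment)
  if (is.null(total_control)) total_control <- sum(cc)
  if (is.null(total_treatment)) total_treatment <- sum(tc)

  rpkm_c <- compute_rpkm(cc, len, total_control)
  rpkm_t <- compute_rpkm(tc, len, total_treatment)
  fold <- compute_rpkm(tc + pseudocount, len, total_treatment) /
    compute_rpkm(cc + pseudocount, len, total_control)

  if (is.null(test_fun)) test_fun <- binomial_count_test
  p <- test_fun(cc, tc, total_control, total_treatment)
  fdr <- benjamini_hochberg(p)

  direction <- rep("unchanged", length(ids))
  direction[fold >= fold_threshold & fdr < fdr_threshold] <- "up"
  direction[fold <= 1 / fold_threshold & fdr < fdr_threshold] <- "down"

  data.frame(id = ids, rpkm_control = rpkm_c, rpkm_treatment = rpkm_t,
             fold_change = fold, p_value = p, fdr = fdr,
             direction = direction, stringsAsFactors = FALSE)
}
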