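#' Pipeline configuration
#'
#' Collects every threshold of the cascade with its default: 2-fold /
#' FDR < 0.001 differential gate, >200 nt and <80 AA non-coding screen,
#' >99% identity and >90% precursor coverage for miRNA-precursor calls,
#' >90% identity and >90% coverage for CDS pairing, >=1 distinct read per
#' library for sRNA support, and tau >= 0.8 for tissue specificity.
#'
#' @param fold_threshold,fdr_threshold Differential-expression gates.
#' @param min_length_nt,max_orf_aa Non-coding screen gates (strict:
#'   retained iff length > `min_length_nt` and ORF < `max_orf_aa`).
#' @param mirna_min_identity,mirna_min_coverage miRNA-precursor gates
#'   (strict >).
#' @param mirna_coverage_side `"precursor"` or `"lncrna"`.
#' @param cds_min_identity,cds_min_coverage CDS-pairing gates (strict >).
#' @param cds_coverage_mode `"max"`, `"both"` or `"query"` (see
#'   [pair_with_cds()]).
#' @param min_reads Distinct-read support needed per sRNA library.
#' @param tau_threshold Tissue-specificity call threshold.
#' @param both_strands Search both strands in read matching.
#' @param strand_precedence Positional-classification precedence (see
#'   [classify_position()]).
#' @param coding_labels Optional external coding/noncoding label table.
#' @return A classed list of settings.
#' @export
lnc_config <- function(fold_threshold = 2, fdr_threshold = 0.001,
                       min_length_nt = 200L, max_orf_aa = 80L,
                       mirna_min_identity = 99, mirna_min_coverage = 90,
                       mirna_coverage_side = "precursor",
                       cds_min_identity = 90, cds_min_coverage = 90,
                       cds_coverage_mode = "max",
                       min_reads = 1L, tau_threshold = 0.8,
                       both_strands = TRUE,
                       strand_precedence = "sense",
                       coding_labels = NULL) {
  stopifnot(fold_threshold >= 1, fdr_threshold > 0, fdr_threshold <= 1,
            min_length_nt >= 0, max_orf_aa >= 1,
            mirna_min_identity >= 0, mirna_min_identity <= 100,
            mirna_min_coverage >= 0, cds_min_identity >= 0,
            cds_min_coverage >= 0, min_reads >= 1,
            tau_threshold >= 0, tau_threshold <= 1)
  structure(list(
    fold_threshold = fold_threshold, fdr_threshold = fdr_threshold,
    min_length_nt = min_length_nt, max_orf_aa = max_orf_aa,
    mirna_min_identity = mirna_min_identity,
    mirna_min_coverage = mirna_min_coverage,
    mirna_coverage_side = mirna_coverage_side,
    cds_min_identity = cds_min_identity,
    cds_min_coverage = cds_min_coverage,
    cds_coverage_mode = cds_coverage_mode,
    min_reads = min_reads, tau_threshold = tau_threshold,
    both_strands = both_strands, strand_precedence = strand_precedence,
    coding_labels = coding_labels), class = "lnc_config")
}

#' @export
print.lnc_config <- function(x, ...) {
  cat("lncRNA screening configuration:\n")
  for (nm in setdiff(names(x), "coding_labels")) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-22s %s\n", "coding_labels",
              if (is.null(x$coding_labels)) "built-in heuristic"
              else paste(length(x$coding_labels), "external labels")))
  invisible(x)
}

## precursor_class x positional_class count matrix with margins
precursor_by_position_matrix <- function(results) {
  prec_levels <- c("miRNA_precursor", "shRNA_siRNA_precursor",
                   "siRNA_precursor", "other")
  pos_levels <- c("intergenic", "intragenic", "antisense", "overlapping")
  tab <- table(factor(results$precursor_class, levels = prec_levels),
               factor(results$positional_class, levels = pos_levels))
  m <- stats::addmargins(tab)
  dimnames(m) <- list(c(prec_levels, "Total"), c(pos_levels, "Total"))
  unclass(m)
}

## positional_class x direction count matrix with margins
position_by_direction_matrix <- function(results) {
  pos_levels <- c("intergenic", "intragenic", "antisense", "overlapping")
  dir_levels <- c("up", "down")
  tab <- table(factor(results$positional_class, levels = pos_levels),
               factor(results$direction, levels = dir_levels))
  m <- stats::addmargins(tab)
  dimnames(m) <- list(c(pos_levels, "Total"), c(dir_levels, "total"))
  unclass(m)
}

#' Summary count matrices of a classified cohort
#'
#' Builds the two headline matrices of the screen: positional class by
#' expression direction, and precursor class by positional class, both
#' with margins.  By construction every margin equals the sum of its
#' cells and both grand totals equal the cohort size (conservation: the
#' four labels of each axis partition the cohort).
#'
#' @param results Data frame with columns `positional_class`,
#'   `precursor_class`, `direction`.
#' @return List with matrices `position_by_direction` and
#'   `precursor_by_position`.
#' @export
summarize_counts <- function(results) {
  list(position_by_direction = position_by_direction_matrix(results),
       precursor_by_position = precursor_by_position_matrix(results))
}

#' Run the full lncRNA identification cascade
#'
#' Executes the stages in order: differential-expression screen ->
#' non-coding filter -> positional classification -> miRNA-precursor
#' alignment -> exact sRNA read matching -> hierarchical precursor
#' classification -> antisense CDS pairing (non-antisense `other`
#' lncRNAs only) -> tissue-specificity scoring.  The result is
#' deterministic given the inputs and configuration.
#'
#' @param x An `lnc_dataset` object (see [simulate_lnc_dataset()]) or a
#'   directory written by [write_lnc_dataset()].
#' @param config An [lnc_config()] object.
#' @param verbose Log per-stage record counts to stderr.
#' @return An object of class `lnc_pipeline`: list with `de` (full DE
#'   table), `candidates` (retained lncRNA ids), `classification` (one
#'   row per lncRNA: `id`, `positional_class`, `precursor_class`,
#'   `direction`, `evidence`, `shrna_only`), `mirna_calls`,
#'   `read_support`, `cds_pairs`, `tissue`, `summary` (see
#'   [summarize_counts()]), `config` and `log` (stage funnel counts).
#' @export
run_pipeline <- function(x, config = lnc_config(), verbose = TRUE) {
  if (is.character(x) && length(x) == 1L) x <- read_lnc_dataset(x)
  stopifnot(inherits(x, "lnc_dataset"), inherits(config, "lnc_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  log <- list(input = length(x$transcripts))
  say("stage de: %d transcripts in", log$input)

  lengths_nt <- stats::setNames(nchar(x$transcripts), names(x$transcripts))
  tc <- if (!is.null(x$total_mapped)) x$total_mapped else NULL
  de <- call_differential(x$counts, lengths_nt,
                          fold_threshold = config$fold_threshold,
                          fdr_threshold = config$fdr_threshold,
                          total_control = tc[["control"]],
                          total_treatment = tc[["treatment"]])
  responsive <- de$id[de$direction != "unchanged"]
  log$responsive <- length(responsive)
  say("stage de: %d drought-responsive transcripts", log$responsive)

  cand_seqs <- filter_lncrna_candidates(
    x$transcripts[responsive],
    min_length_nt = config$min_length_nt, max_orf_aa = config$max_orf_aa,
    coding_labels = config$coding_labels)
  candidates <- names(cand_seqs)
  log$candidates <- length(candidates)
  say("stage filter: %d lncRNA candidates", log$candidates)

  loci <- x$loci[x$loci$id %in% candidates, , drop = FALSE]
  positions <- classify_position(loci, x$annotation,
                                 strand_precedence = config$strand_precedence)
  say("stage position: %d classified", nrow(positions))

  mirna_calls <- classify_mirna_precursor(
    cand_seqs, x$precursors,
    min_identity_pct = config$mirna_min_identity,
    min_precursor_cov_pct = config$mirna_min_coverage,
    coverage_side = config$mirna_coverage_side)
  say("stage mirna: %d precursor hosts", length(unique(mirna_calls$lncrna_id)))

  matches <- match_reads_exact(cand_seqs, x$reads,
                               both_strands = config$both_strands)
  classes <- hierarchical_classify(candidates, mirna_calls, matches$support,
                                   min_reads = config$min_reads)
  say("stage hierarchy: %s",
      paste(names(table(classes$precursor_class)),
            table(classes$precursor_class), collapse = ", ", sep = "="))

  classification <- merge(
    merge(classes, positions[, c("id", "positional_class")], by = "id"),
    de[, c("id", "direction")], by = "id")
  classification <- classification[match(candidates, classification$id), ,
                                   drop = FALSE]
  rownames(classification) <- NULL

  other_nonanti <- classification$id[
    classification$precursor_class == "other" &
      classification$positional_class != "antisense"]
  cds_pairs <- if (length(other_nonanti) && length(x$cds)) {
    pair_with_cds(x$transcripts[other_nonanti], x$cds,
                  min_identity_pct = config$cds_min_identity,
                  min_cov_pct = config$cds_min_coverage,
                  coverage_mode = config$cds_coverage_mode)
  } else {
    pair_with_cds(character(), c(dummy = "A"))[0, ]
  }
  say("stage cds: %d passing pairs", nrow(cds_pairs))

  tissue <- NULL
  if (!is.null(x$tissue)) {
    keep <- rownames(x$tissue) %in% candidates
    if (any(keep)) {
      tissue <- tissue_specificity(x$tissue[keep, , drop = FALSE],
                                   threshold = config$tau_threshold)
    }
  }

  res <- structure(list(
    de = de, candidates = candidates, classification = classification,
    mirna_calls = mirna_calls, read_support = matches$support,
    read_positions = matches$positions, cds_pairs = cds_pairs,
    tissue = tissue, summary = summarize_counts(classification),
    config = config, log = log), class = "lnc_pipeline")
  res
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  cat("lncRNA identification cascade\n")
  cat(sprintf("  %d transcripts -> %d responsive -> %d lncRNA candidates\n",
              x$log$input, x$log$responsive, x$log$candidates))
  tab <- x$summary$precursor_by_position
  cat("  taxonomy (precursor class x positional class):\n")
  print(tab)
  cat(sprintf("  CDS pairs passing: %d\n", nrow(x$cds_pairs)))
  if (!is.null(x$tissue)) {
    cat(sprintf("  tissue-specific lncRNAs: %d of %d profiled\n",
                sum(!is.na(x$tissue$specific_tissue)), nrow(x$tissue)))
  }
  invisible(x)
}

#' @method summary lnc_pipeline
#' @export
summary.lnc_pipeline <- function(object, ...) {
  object$summary
}

#' Write every pipeline output table to a directory
#'
#' @param result An `lnc_pipeline` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  stopifnot(inherits(result, "lnc_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(result$de, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_classification_table(result$classification, p("classification.tsv"))
  table4_report(result$cds_pairs, p("cds_pairs.tsv"))
  if (!is.null(result$tissue)) {
    utils::write.table(result$tissue, p("tissue_tau.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (nm in names(result$summary)) {
    utils::write.table(result$summary[[nm]], p(paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}
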