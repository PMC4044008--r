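#' Antisense pairing of lncRNAs with CDS sequences
#'
#' Aligns each lncRNA against each CDS in plus/minus orientation (the
#' lncRNA versus the reverse complement of the CDS -- the antisense
#' pattern; set `orientation = "plus/plus"` to search sense pairings
#' instead) and reports every pair together with its alignment
#' statistics.  A pair passes the near-perfect-match gate iff identity
#' strictly exceeds `min_identity_pct` and the coverage statistic chosen
#' by `coverage_mode` strictly exceeds `min_cov_pct`:
#'
#' * `"max"` (default): the larger of the two per-side coverages -- a
#'   short lncRNA fully covering a CDS, or vice versa, qualifies;
#' * `"both"`: both sides must exceed the gate;
#' * `"query"`: lncRNA-side coverage only.
#'
#' The default is `"max"` because a near-perfect antisense match between
#' sequences of very different lengths necessarily leaves the longer
#' side's coverage low.  One lncRNA may pair with many CDS and one CDS
#' with many lncRNAs.
#'
#' @param other_lncrnas Named character vector of lncRNA sequences
#'   (normally the non-antisense members of the `other` precursor class).
#' @param cds_set Named character vector of CDS sequences.
#' @param min_identity_pct Identity gate (default 90).
#' @param min_cov_pct Coverage gate (default 90).
#' @param coverage_mode See above.
#' @param orientation Alignment orientation (default `"plus/minus"`).
#' @param passing_only Keep only pairs that pass the gate (default TRUE).
#' @param ... Scoring parameters forwarded to [align_local()].
#' @return Data frame with one row per (reported) pair: `lncrna_id`,
#'   `cds_id`, `query_len`, `subject_len`, `hit_len`, `identity_pct`,
#'   `query_cov_pct`, `subject_cov_pct`, `orientation`,
#'   `passes_threshold`.
#' @export
pair_with_cds <- function(other_lncrnas, cds_set,
                          min_identity_pct = 90, min_cov_pct = 90,
                          coverage_mode = c("max", "both", "query"),
                          orientation = "plus/minus",
                          passing_only = TRUE, ...) {
  coverage_mode <- match.arg(coverage_mode)
  if (length(cds_set) == 0L) stop("CDS set is empty")
  rows <- list()
  for (lid in names(other_lncrnas)) {
    for (cid in names(cds_set)) {
      hit <- align_local(other_lncrnas[[lid]], cds_set[[cid]],
                         orientation = orientation,
                         query_id = lid, subject_id = cid, ...)
      if (hit$hit_len == 0L) next
      cov <- switch(coverage_mode,
                    max = max(hit$query_cov_pct, hit$subject_cov_pct),
                    both = min(hit$query_cov_pct, hit$subject_cov_pct),
                    query = hit$query_cov_pct)
      passes <- hit$identity_pct > min_identity_pct && cov > min_cov_pct
      if (passes || !passing_only) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncrna_id = lid, cds_id = cid,
          query_len = nchar(other_lncrnas[[lid]]),
          subject_len = nchar(cds_set[[cid]]),
          hit_len = hit$hit_len, identity_pct = hit$identity_pct,
          query_cov_pct = hit$query_cov_pct,
          subject_cov_pct = hit$subject_cov_pct,
          orientation = orientation, passes_threshold = passes,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(lncrna_id = character(), cds_id = character(),
                      query_len = integer(), subject_len = integer(),
                      hit_len = integer(), identity_pct = numeric(),
                      query_cov_pct = numeric(), subject_cov_pct = numeric(),
                      orientation = character(), passes_threshold = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Report lncRNA-CDS pairs as a standard alignment table
#'
#' One row per pair with the columns `Query_name`, `Hit_name`,
#' `Query_len`, `Sbject_len`, `Hit_len`, `Percent_identity`,
#' `Percent_query_aligned`, `Percent_Sbject_aligned`; percentages rounded
#' to 2 decimals.  The two coverage columns satisfy
#' `Percent_query_aligned * Query_len == Percent_Sbject_aligned *
#' Sbject_len` up to rounding (both equal `100 * Hit_len`).
#'
#' @param pairs Data frame from [pair_with_cds()].
#' @param path Optional output path; when given, the table is written as
#'   TSV.
#' @return The report data frame (invisibly when `path` is given).
#' @export
table4_report <- function(pairs, path = NULL) {
  cov <- coverage_stats(pmax(pairs$query_len, 1L),
                        pmax(pairs$subject_len, 1L), pairs$hit_len)
  if (nrow(pairs) == 0L) {
    report <- data.frame(Query_name = character(), Hit_name = character(),
                         Query_len = integer(), Sbject_len = integer(),
                         Hit_len = integer(), Percent_identity = numeric(),
                         Percent_query_aligned = numeric(),
                         Percent_Sbject_aligned = numeric(),
                         stringsAsFactors = FALSE)
  } else {
    if (length(pairs$query_len) == 1L) cov <- matrix(cov, nrow = 1L,
      dimnames = list(NULL, c("query_cov_pct", "subject_cov_pct")))
    report <- data.frame(
      Query_name = pairs$lncrna_id, Hit_name = pairs$cds_id,
      Query_len = pairs$query_len, Sbject_len = pairs$subject_len,
      Hit_len = pairs$hit_len,
      Percent_identity = round(pairs$identity_pct, 2),
      Percent_query_aligned = cov[, "query_cov_pct"],
      Percent_Sbject_aligned = cov[, "subject_cov_pct"],
      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}
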