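#' Local alignment of two nucleotide sequences
#'
#' Smith-Waterman optimal local alignment with affine gap costs
#' (defaults: match +2, mismatch -3, gap open -5, gap extend -2; a
#' k-column gap scores `gap_open + (k-1) * gap_extend`).  In
#' `"plus/minus"` orientation the query is aligned against the reverse
#' complement of the subject (the antisense search pattern).  `hit_len`
#' counts all alignment columns including gap columns, which is why a
#' coverage percentage computed from it can exceed 100.  Traceback is
#' deterministic: ties prefer the diagonal, then the gap consuming the
#' query, then the gap consuming the subject.
#'
#' @param query,subject Single nucleotide strings over `{A,C,G,T,N}`.
#' @param orientation `"plus/plus"` (default) or `"plus/minus"`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param query_id,subject_id Optional labels carried into the hit.
#' @return A list of class `alignment_hit`: `query_id`, `subject_id`,
#'   `score`, `hit_len` (alignment columns, gaps included), `matches`
#'   (identical columns), `identity_pct` (`100 * matches / hit_len`),
#'   `query_cov_pct` (`100 * hit_len / nchar(query)`), `subject_cov_pct`
#'   (`100 * hit_len / nchar(subject)`), `orientation`, and the 1-based
#'   aligned spans `query_start/end`, `subject_start/end` (subject span
#'   reported on the original subject strand).  When no positive-scoring
#'   alignment exists, `hit_len` is 0 and the percentages are 0.
#' @export
#' @examples
#' hit <- align_local("ACGTACGT", "ACGTACGT")
#' hit$identity_pct  # 100
align_local <- function(query, subject,
                        orientation = c("plus/plus", "plus/minus"),
                        match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -2,
                        query_id = NA_character_, subject_id = NA_character_) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(query), length(query) == 1L,
            is.character(subject), length(subject) == 1L)
  if (!nzchar(query) || !nzchar(subject)) {
    stop("empty sequence in align_local")
  }
  subj_used <- if (orientation == "plus/minus") revcomp(subject) else subject
  raw <- .sw_align_cpp(query, subj_used, match = match, mismatch = mismatch,
                       gap_open = gap_open, gap_extend = gap_extend)
  qlen <- nchar(query)
  slen <- nchar(subject)
  ss <- raw$subject_start
  se <- raw$subject_end
  if (orientation == "plus/minus" && raw$hit_len > 0L) {
    ## report the span on the original subject strand
    tmp <- ss
    ss <- slen - se + 1L
    se <- slen - tmp + 1L
  }
  structure(list(
    query_id = query_id, subject_id = subject_id,
    score = raw$score, hit_len = raw$hit_len, matches = raw$matches,
    identity_pct = if (raw$hit_len > 0L) 100 * raw$matches / raw$hit_len else 0,
    query_cov_pct = if (raw$hit_len > 0L) 100 * raw$hit_len / qlen else 0,
    subject_cov_pct = if (raw$hit_len > 0L) 100 * raw$hit_len / slen else 0,
    orientation = orientation,
    query_start = raw$query_start, query_end = raw$query_end,
    subject_start = ss, subject_end = se
  ), class = "alignment_hit")
}

#' Per-side alignment coverage percentages
#'
#' `(100 * hit_len / query_len, 100 * hit_len / subject_len)`, each
#' rounded to 2 decimals for reporting.  `hit_len` counts alignment
#' columns including gaps, so a coverage can exceed 100 when gap columns
#' inflate the alignment beyond the sequence length.
#'
#' @param query_len,subject_len Sequence lengths (positive).
#' @param hit_len Alignment column count.
#' @return Named numeric vector (or two-column matrix for vector input)
#'   with `query_cov_pct` and `subject_cov_pct`.
#' @export
#' @examples
#' coverage_stats(1258, 246, 254)  # 20.19, 103.25
coverage_stats <- function(query_len, subject_len, hit_len) {
  if (any(query_len <= 0) || any(subject_len <= 0)) {
    stop("sequence lengths must be positive")
  }
  q <- round(100 * hit_len / query_len, 2)
  s <- round(100 * hit_len / subject_len, 2)
  if (length(q) == 1L) {
    c(query_cov_pct = q, subject_cov_pct = s)
  } else {
    cbind(query_cov_pct = q, subject_cov_pct = s)
  }
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("local alignment (%s): score %.1f, %d columns, %.2f%% identity\n",
              x$orientation, x$score, x$hit_len, x$identity_pct))
  cat(sprintf("  query  %s [%d-%d]  coverage %.2f%%\n",
              ifelse(is.na(x$query_id), "", x$query_id),
              x$query_start, x$query_end, x$query_cov_pct))
  cat(sprintf("  subject %s [%d-%d]  coverage %.2f%%\n",
              ifelse(is.na(x$subject_id), "", x$subject_id),
              x$subject_start, x$subject_end, x$subject_cov_pct))
  invisible(x)
}
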