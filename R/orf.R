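#' Longest open reading frame in the forward frames
#'
#' Scans the three forward reading frames of a transcript (assembled
#' transcripts carry strand, so reverse-frame ORFs are not considered).
#' An ORF is an `ATG` followed by an in-frame stop codon
#' (`TAA`/`TAG`/`TGA`); an `ATG` running off the 3' end without a stop is
#' not counted.  Codons containing `N` match neither `ATG` nor a stop.
#' `aa_length` counts the peptide: initiating Met included, stop codon
#' excluded (`"ATGAAATAA"` has `aa_length` 2).  Ties on length are broken
#' by the smallest start offset, then the smallest frame.
#'
#' @param sequence A single nucleotide string over `{A,C,G,T,N}`.
#' @return A list with `frame` (0/1/2), `start_nt` (0-based offset of the
#'   `ATG`), `aa_length`, `has_stop` (always `TRUE`), or `NULL` when the
#'   sequence contains no ORF.
#' @export
find_longest_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    first <- frame + 1L
    if (n - first + 1L < 3L) next
    starts_nt <- seq.int(first, n - 2L, by = 3L)
    codons <- substring(sequence, starts_nt, starts_nt + 2L)
    atg_idx <- which(codons == "ATG")
    stop_idx <- which(codons %in% stops)
    if (!length(atg_idx) || !length(stop_idx)) next
    for (a in atg_idx) {
      s <- stop_idx[stop_idx > a]
      if (!length(s)) next
      aa <- s[1L] - a
      start_nt <- starts_nt[a] - 1L
      if (is.null(best) || aa > best$aa_length ||
          (aa == best$aa_length && start_nt < best$start_nt)) {
        best <- list(frame = frame, start_nt = start_nt,
                     aa_length = aa, has_stop = TRUE)
      }
    }
  }
  best
}

#' Built-in coding-potential heuristic
#'
#' Pluggable stand-in for an external coding/non-coding classifier.  The
#' built-in rule labels a transcript `coding` iff the longest-ORF
#' nucleotide span (ATG through stop codon inclusive, i.e.
#' `3 * (aa_length + 1)` nt) exceeds `max_orf_fraction` of the transcript
#' length, or the longest ORF is at least `min_coding_aa` amino acids.
#' External classifier output can be injected instead via the
#' `coding_labels` argument of [filter_lncrna_candidates()], which
#' overrides this heuristic verbatim.
#'
#' @param sequence A single nucleotide string.
#' @param max_orf_fraction Span fraction above which the transcript is
#'   called coding (default 0.5).
#' @param min_coding_aa ORF length (AA) at or above which the transcript
#'   is called coding regardless of span fraction (default 100).
#' @return List with `label` (`"coding"`/`"noncoding"`) and `score` (the
#'   ORF span fraction; 0 when there is no ORF).
#' @export
coding_potential_score <- function(sequence, max_orf_fraction = 0.5,
                                   min_coding_aa = 100L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  orf <- find_longest_orf(sequence)
  if (is.null(orf)) return(list(label = "noncoding", score = 0))
  span <- 3 * (orf$aa_length + 1L)
  score <- span / nchar(sequence)
  coding <- score > max_orf_fraction || orf$aa_length >= min_coding_aa
  list(label = if (coding) "coding" else "noncoding", score = score)
}

#' Length / ORF screen for lncRNA candidates
#'
#' Retains transcripts with length strictly greater than `min_length_nt`
#' and longest forward-frame ORF strictly shorter than `max_orf_aa` amino
#' acids (no ORF at all also passes).  Transcripts labelled `coding` --
#' either by the built-in heuristic or by a supplied external label table
#' -- are removed first, mirroring a classifier-then-screen cascade.
#' The filter is idempotent and invariant to input order.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param min_length_nt Length gate; retained iff `length > min_length_nt`
#'   (default 200, i.e. ">200 nt").
#' @param max_orf_aa ORF gate; retained iff longest ORF `< max_orf_aa`
#'   (default 80, i.e. "<80 AA").
#' @param coding_labels Optional named character vector
#'   (`"coding"`/`"noncoding"`) from an external classifier; ids present
#'   here use the external label verbatim, others fall back to
#'   [coding_potential_score()].
#' @param max_orf_fraction,min_coding_aa Passed to the built-in heuristic.
#' @return Named character vector: the retained transcripts, input order
#'   preserved.
#' @export
filter_lncrna_candidates <- function(transcripts, min_length_nt = 200L,
                                     max_orf_aa = 80L, coding_labels = NULL,
                                     max_orf_fraction = 0.5,
                                     min_coding_aa = 100L) {
  stopifnot(is.character(transcripts))
  if (length(transcripts) == 0L) return(transcripts)
  if (is.null(names(transcripts)) || any(!nzchar(names(transcripts)))) {
    stop("transcripts must be a named character vector")
  }
  ids <- names(transcripts)
  keep <- vapply(ids, function(id) {
    seq <- transcripts[[id]]
    label <- if (!is.null(coding_labels) && id %in% names(coding_labels)) {
      coding_labels[[id]]
    } else {
      coding_potential_score(seq, max_orf_fraction, min_coding_aa)$label
    }
    if (identical(label, "coding")) return(FALSE)
    if (nchar(seq) <= min_length_nt) return(FALSE)
    orf <- find_longest_orf(seq)
    is.null(orf) || orf$aa_length < max_orf_aa
  }, logical(1L))
  transcripts[keep]
}
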