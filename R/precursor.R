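#' miRNA-precursor calls by local alignment
#'
#' Aligns every miRNA precursor against every lncRNA (both orientations,
#' best score kept) and labels an lncRNA a miRNA precursor host iff some
#' precursor aligns with identity strictly greater than
#' `min_identity_pct` and precursor (subject) coverage strictly greater
#' than `min_precursor_cov_pct`.  One lncRNA may host several precursors
#' and one precursor may be hosted by several lncRNAs; every qualifying
#' pair is reported.  Classification uses unrounded percentages.
#'
#' @param lncrnas Named character vector of lncRNA sequences.
#' @param precursor_library Named character vector of precursor sequences
#'   (miRBase-style ids).
#' @param min_identity_pct Identity gate (default 99, i.e. ">99%").
#' @param min_precursor_cov_pct Coverage gate on the precursor side
#'   (default 90, i.e. ">90%").
#' @param coverage_side Which side the coverage gate applies to:
#'   `"precursor"` (default) or `"lncrna"`.
#' @param ... Scoring parameters forwarded to [align_local()].
#' @return Data frame of qualifying calls: `lncrna_id`, `precursor_id`,
#'   `identity_pct`, `coverage_pct`, `hit_len`, `orientation`.
#' @export
classify_mirna_precursor <- function(lncrnas, precursor_library,
                                     min_identity_pct = 99,
                                     min_precursor_cov_pct = 90,
                                     coverage_side = c("precursor", "lncrna"),
                                     ...) {
  coverage_side <- match.arg(coverage_side)
  if (length(precursor_library) == 0L) stop("precursor library is empty")
  rows <- list()
  for (lid in names(lncrnas)) {
    for (pid in names(precursor_library)) {
      hits <- lapply(c("plus/plus", "plus/minus"), function(ori) {
        align_local(precursor_library[[pid]], lncrnas[[lid]],
                    orientation = ori, query_id = pid, subject_id = lid, ...)
      })
      hit <- hits[[which.max(vapply(hits, `[[`, numeric(1L), "score"))]]
      ## precursor is the alignment query here; its coverage is query_cov
      cov <- if (coverage_side == "precursor") hit$query_cov_pct else hit$subject_cov_pct
      if (hit$hit_len > 0L && hit$identity_pct > min_identity_pct &&
          cov > min_precursor_cov_pct) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncrna_id = lid, precursor_id = pid,
          identity_pct = hit$identity_pct, coverage_pct = cov,
          hit_len = hit$hit_len, orientation = hit$orientation,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(lncrna_id = character(), precursor_id = character(),
                      identity_pct = numeric(), coverage_pct = numeric(),
                      hit_len = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Exact (zero-mismatch) matching of small-RNA reads to lncRNAs
#'
#' A read supports an lncRNA iff its sequence occurs as an exact
#' substring of the lncRNA or (by default) of its reverse complement --
#' the exact-substring semantics of zero-mismatch short-read mapping.
#' All occurrence offsets are recorded; `distinct_reads` counts unique
#' read sequences per (lncRNA, library).
#'
#' @param lncrnas Named character vector of lncRNA sequences.
#' @param reads Data frame with columns `read_id`, `sequence`, `library`
#'   (e.g. `"shRNA"`/`"siRNA"`); see [srna_read_table()].
#' @param both_strands Also search the reverse complement (default TRUE;
#'   siRNA duplexes yield reads of both polarities).
#' @param min_len,max_len Permitted read length bounds (default 18-30 nt).
#' @return List with `positions` (data.frame: `lncrna_id`, `read_id`,
#'   `library`, `offset` 0-based on the lncRNA sense strand, `strand`
#'   `"sense"`/`"antisense"`) and `support` (data.frame: `lncrna_id`,
#'   `library`, `distinct_reads`).
#' @export
match_reads_exact <- function(lncrnas, reads, both_strands = TRUE,
                              min_len = 18L, max_len = 30L) {
  stopifnot(all(c("read_id", "sequence", "library") %in% names(reads)))
  empty <- list(
    positions = data.frame(lncrna_id = character(), read_id = character(),
                           library = character(), offset = integer(),
                           strand = character(), stringsAsFactors = FALSE),
    support = data.frame(lncrna_id = character(), library = character(),
                         distinct_reads = integer(), stringsAsFactors = FALSE))
  if (nrow(reads) == 0L || length(lncrnas) == 0L) return(empty)
  widths <- nchar(reads$sequence)
  if (any(widths < min_len | widths > max_len)) {
    stop("read length outside [", min_len, ", ", max_len, "] nt: ",
         reads$read_id[which(widths < min_len | widths > max_len)[1L]])
  }

  subjects <- lapply(lncrnas, Biostrings::DNAString)
  rc_subjects <- if (both_strands) lapply(lncrnas, function(s)
    Biostrings::DNAString(revcomp(s))) else NULL
  lnc_len <- nchar(lncrnas)

  pos <- list()
  ## group reads by width so a constant-width PDict can be used per group
  for (w in sort(unique(widths))) {
    grp <- which(widths == w)
    pdict <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence[grp]))
    for (k in seq_along(lncrnas)) {
      lid <- names(lncrnas)[k]
      m <- Biostrings::matchPDict(pdict, subjects[[k]])
      starts <- Biostrings::startIndex(m)
      for (r in seq_along(grp)) {
        st <- starts[[r]]
        if (length(st)) {
          pos[[length(pos) + 1L]] <- data.frame(
            lncrna_id = lid, read_id = reads$read_id[grp[r]],
            library = reads$library[grp[r]], offset = st - 1L,
            strand = "sense", stringsAsFactors = FALSE)
        }
      }
      if (both_strands) {
        m2 <- Biostrings::matchPDict(pdict, rc_subjects[[k]])
        starts2 <- Biostrings::startIndex(m2)
        for (r in seq_along(grp)) {
          st <- starts2[[r]]
          if (length(st)) {
            ## offset on the sense strand of the lncRNA
            pos[[length(pos) + 1L]] <- data.frame(
              lncrna_id = lid, read_id = reads$read_id[grp[r]],
              library = reads$library[grp[r]],
              offset = lnc_len[k] - (st - 1L) - w,
              strand = "antisense", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(pos) == 0L) return(empty)
  positions <- do.call(rbind, pos)
  rownames(positions) <- NULL

  seq_by_read <- stats::setNames(reads$sequence, reads$read_id)
  key <- unique(positions[, c("lncrna_id", "library", "read_id")])
  key$read_seq <- seq_by_read[key$read_id]
  key <- unique(key[, c("lncrna_id", "library", "read_seq")])
  agg <- stats::aggregate(read_seq ~ lncrna_id + library, data = key, FUN = length)
  names(agg)[3L] <- "distinct_reads"
  list(positions = positions, support = agg)
}

#' Combine per-library sRNA read sets into one read table
#'
#' @param ... Named arguments, one per library (e.g. `shRNA = reads1,
#'   siRNA = reads2`), each a named character vector of read sequences as
#'   returned by [read_fasta()].
#' @return Data frame with columns `read_id`, `sequence`, `library`.
#' @export
srna_read_table <- function(...) {
  libs <- list(...)
  if (is.null(names(libs)) || any(!nzchar(names(libs)))) {
    stop("each read library must be passed as a named argument")
  }
  do.call(rbind, lapply(names(libs), function(nm) {
    v <- libs[[nm]]
    data.frame(read_id = names(v), sequence = unname(v), library = nm,
               stringsAsFactors = FALSE)
  }))
}

#' Hierarchical precursor classification
#'
#' Applies the fixed precursor taxonomy, first matching rule wins:
#' `miRNA_precursor` if the lncRNA has a qualifying precursor alignment;
#' else `shRNA_siRNA_precursor` if it is supported by at least
#' `min_reads` distinct reads in *both* the shRNA and siRNA libraries;
#' else `siRNA_precursor` if supported in the siRNA library alone; else
#' `other`.  The taxonomy has no shRNA-only class; an lncRNA with shRNA
#' support but no siRNA support falls to `other` and is flagged in the
#' `shrna_only` column so the anomaly is visible in output.
#'
#' @param lncrna_ids Character vector of lncRNA ids to classify.
#' @param mirna_calls Data frame from [classify_mirna_precursor()].
#' @param read_support Data frame `support` from [match_reads_exact()].
#' @param min_reads Minimum distinct reads per library (default 1).
#' @return Data frame: `id`, `precursor_class`, `evidence` (summary
#'   string), `shrna_only` (logical flag).
#' @export
hierarchical_classify <- function(lncrna_ids, mirna_calls, read_support,
                                  min_reads = 1L) {
  support_of <- function(id, lib) {
    hit <- read_support$lncrna_id == id & read_support$library == lib
    if (any(hit)) sum(read_support$distinct_reads[hit]) else 0L
  }
  rows <- lapply(lncrna_ids, function(id) {
    n_sh <- support_of(id, "shRNA")
    n_si <- support_of(id, "siRNA")
    mi <- mirna_calls$precursor_id[mirna_calls$lncrna_id == id]
    if (length(mi)) {
      cls <- "miRNA_precursor"
      ev <- paste0("precursor:", paste(mi, collapse = ","))
    } else if (n_sh >= min_reads && n_si >= min_reads) {
      cls <- "shRNA_siRNA_precursor"
      ev <- sprintf("shRNA_reads:%d;siRNA_reads:%d", n_sh, n_si)
    } else if (n_si >= min_reads) {
      cls <- "siRNA_precursor"
      ev <- sprintf("siRNA_reads:%d", n_si)
    } else {
      cls <- "other"
      ev <- if (n_sh >= min_reads) sprintf("shRNA_reads:%d", n_sh) else ""
    }
    data.frame(id = id, precursor_class = cls, evidence = ev,
               shrna_only = cls == "other" && n_sh >= min_reads,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
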