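#' Read a nucleotide FASTA file
#'
#' Reads a FASTA file into a named character vector of uppercase sequences.
#' Record ids are taken up to the first whitespace character (the common
#' behaviour of alignment tools), record order is preserved, and sequences
#' are validated against the strict alphabet `{A,C,G,T,N}` -- other IUPAC
#' ambiguity codes are rejected rather than silently remapped, because the
#' downstream read-matching stage relies on exact-string semantics.
#'
#' @param path Path to a FASTA file.
#' @param on_duplicate What to do when the same id occurs twice:
#'   `"error"` (default) or `"warn"` (keeps both records; names will be
#'   non-unique).
#' @return Named character vector (`names` = ids, values = sequences).
#' @export
read_fasta <- function(path, on_duplicate = c("error", "warn")) {
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    msg <- paste0("duplicate FASTA id(s): ", paste(dups, collapse = ", "))
    if (on_duplicate == "error") stop(msg) else warning(msg)
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence(s) with characters outside {A,C,G,T,N}: ",
         paste(ids[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

## Strict structural validation of GFF3 lines; rtracklayer does the actual
## parsing afterwards, but its errors for truncated lines are not
## informative enough for pipeline input checking.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) return(invisible(TRUE))
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    stop("GFF3 format error: line(s) with ", nfield[nfield != 9L][1L],
         " columns (9 required), e.g.: ",
         substr(body[nfield != 9L][1L], 1L, 80L))
  }
  fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  starts <- suppressWarnings(as.integer(fields[, 4L]))
  ends <- suppressWarnings(as.integer(fields[, 5L]))
  if (anyNA(starts) || anyNA(ends)) {
    stop("GFF3 format error: non-integer start/end coordinate")
  }
  if (any(ends < starts)) stop("GFF3 format error: end < start")
  if (any(starts < 1L)) stop("GFF3 format error: coordinates must be >= 1")
  invisible(TRUE)
}

#' Read a GFF3 genome annotation
#'
#' Extracts `gene` features (the annotation used for positional
#' classification) and, when present, `transcript`/`mRNA` features (the
#' assembled isoform loci).  GFF3 coordinates are 1-based inclusive;
#' internally everything is converted to 0-based half-open intervals so
#' that overlap arithmetic has no off-by-one ambiguity.  Strand must be
#' `+` or `-` for every feature retained.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `genome_annotation`: a list with
#'   `genes` (data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`) and `transcripts` (data.frame: `id`, `chrom`, `start`,
#'   `end`, `strand`), both 0-based half-open.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  strand <- as.character(BiocGenerics::strand(gr))

  pick <- function(keep) {
    if (!any(keep)) {
      return(data.frame(id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    if (any(!strand[keep] %in% c("+", "-"))) {
      stop("GFF3 feature without explicit +/- strand")
    }
    ids <- if ("ID" %in% names(md)) as.character(md$ID[keep]) else
      paste0("feature_", which(keep))
    data.frame(id = ids,
               chrom = as.character(GenomicRanges::seqnames(gr))[keep],
               start = BiocGenerics::start(gr)[keep] - 1L,  # to 0-based
               end = BiocGenerics::end(gr)[keep],           # half-open
               strand = strand[keep],
               stringsAsFactors = FALSE)
  }

  genes <- pick(type == "gene")
  names(genes)[1L] <- "gene_id"
  genes$biotype <- if ("biotype" %in% names(md)) {
    bt <- as.character(md$biotype[type == "gene"])
    ifelse(is.na(bt) | bt == "protein_coding", "protein_coding", "other")
  } else rep("protein_coding", nrow(genes))

  transcripts <- pick(type %in% c("transcript", "mRNA"))
  structure(list(genes = genes, transcripts = transcripts),
            class = "genome_annotation")
}

#' Write a genome annotation to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open intervals are
#' re-emitted as 1-based inclusive GFF3 coordinates.
#'
#' @param annotation A `genome_annotation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  t <- annotation$transcripts
  fmt <- function(df, type, id_col, extra = "") {
    if (nrow(df) == 0L) return(character())
    attr_str <- paste0("ID=", df[[id_col]], extra)
    paste(df$chrom, "lncscreen", type, df$start + 1L, df$end, ".",
          df$strand, ".", attr_str, sep = "\t")
  }
  lines <- c("##gff-version 3",
             fmt(g, "gene", "gene_id", paste0(";biotype=", g$biotype)),
             fmt(t, "transcript", "id"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-transcript count table
#'
#' The table must be tab-separated with a header row; the first column
#' holds transcript ids and every other column name must begin with
#' `control` or `treatment` (e.g. `control_1`, `treatment_2`), which is
#' how replicates are assigned to conditions.  Counts must be
#' non-negative integers.  Transcripts absent from the table stay absent
#' (they are not zero-filled).
#'
#' @param path Path to the counts TSV.
#' @return An object of class `count_table`: list with `ids` and integer
#'   matrices `control` and `treatment` (rows = transcripts).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("counts table needs an id column plus >=1 column per condition")
  cond <- ifelse(grepl("^control", names(df)[-1L], ignore.case = TRUE), "control",
          ifelse(grepl("^treatment", names(df)[-1L], ignore.case = TRUE), "treatment", NA))
  if (anyNA(cond)) {
    stop("count column names must start with 'control' or 'treatment': ",
         paste(names(df)[-1L][is.na(cond)], collapse = ", "))
  }
  if (!any(cond == "control") || !any(cond == "treatment")) {
    stop("counts table must contain both control and treatment columns")
  }
  if (nrow(df) == 0L) {
    warning("counts table has no rows")
    return(structure(list(ids = character(),
                          control = matrix(integer(), 0, sum(cond == "control")),
                          treatment = matrix(integer(), 0, sum(cond == "treatment"))),
                     class = "count_table"))
  }
  counts <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric count value in ", path)
  if (any(counts < 0)) stop("negative count value in ", path)
  if (any(counts != round(counts))) stop("non-integer count value in ", path)
  mode(counts) <- "integer"
  structure(list(ids = as.character(df[[1L]]),
                 control = counts[, cond == "control", drop = FALSE],
                 treatment = counts[, cond == "treatment", drop = FALSE]),
            class = "count_table")
}

#' Write a count table
#'
#' @param counts A `count_table` object (see [read_counts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  df <- data.frame(id = counts$ids, stringsAsFactors = FALSE)
  cc <- counts$control
  tc <- counts$treatment
  colnames(cc) <- paste0("control_", seq_len(ncol(cc)))
  colnames(tc) <- paste0("treatment_", seq_len(ncol(tc)))
  df <- cbind(df, cc, tc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-lncRNA classification table
#'
#' Emits a TSV with columns `id`, `positional_class`, `precursor_class`,
#' `direction`, `evidence`, followed by a commented summary block giving
#' the precursor-class-by-positional-class count matrix (margins
#' included), so the headline taxonomy can be read off the file directly.
#'
#' @param results Data frame with at least the five columns above.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_table <- function(results, path) {
  need <- c("id", "positional_class", "precursor_class", "direction", "evidence")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols)) {
    stop("classification results missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(results[, need, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- precursor_by_position_matrix(results)
  writeLines("# summary: precursor_class x positional_class", con)
  writeLines(paste0("# \t", paste(colnames(summ), collapse = "\t")), con)
  for (i in seq_len(nrow(summ))) {
    writeLines(paste0("# ", rownames(summ)[i], "\t",
                      paste(summ[i, ], collapse = "\t")), con)
  }
  invisible(path)
}

## Reverse complement over {A,C,G,T,N}; used throughout for plus/minus
## alignment and minus-strand read matching.
#' Reverse complement of a DNA string
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
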