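#' Positional classification of transcripts against a gene annotation
#'
#' Assigns each transcript exactly one of four positional classes by a
#' decision cascade on gene-span overlap (half-open intervals, >=1 shared
#' nt; gene spans, not exon models, so intronic transcripts count as
#' intragenic):
#'
#' 1. no overlap with any gene -> `intergenic`;
#' 2. overlap only with opposite-strand gene(s) -> `antisense`;
#' 3. same-strand overlap with the transcript fully contained in one
#'    gene's span -> `intragenic`;
#' 4. same-strand overlap crossing a gene boundary -> `overlapping`.
#'
#' When both same- and opposite-strand overlaps exist, the same-strand
#' relation wins by default (`strand_precedence = "sense"`); set
#' `"antisense"` to let any opposite-strand overlap dominate.  The
#' supporting gene is the one with maximal overlap among the strand class
#' that decided the label; ties break to the gene with the smaller start.
#' Chromosomes absent from the annotation are treated as gene-free.
#'
#' @param loci Data frame of transcript loci with columns `id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`).
#' @param annotation A `genome_annotation` object (see [read_gff3()]) or
#'   a gene data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param strand_precedence Which overlap class decides when both exist.
#' @return Data frame with columns `id`, `positional_class`
#'   (`intergenic`/`intragenic`/`antisense`/`overlapping`),
#'   `supporting_gene` (`NA` for intergenic), `overlap_nt`.
#' @export
classify_position <- function(loci, annotation,
                              strand_precedence = c("sense", "antisense")) {
  strand_precedence <- match.arg(strand_precedence)
  genes <- if (inherits(annotation, "genome_annotation")) annotation$genes else annotation
  stopifnot(all(c("id", "chrom", "start", "end", "strand") %in% names(loci)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (any(loci$end <= loci$start)) {
    stop("malformed transcript interval (end <= start): ",
         paste(loci$id[loci$end <= loci$start][1L]))
  }
  if (!all(loci$strand %in% c("+", "-")) || !all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }

  out <- data.frame(id = loci$id,
                    positional_class = rep("intergenic", nrow(loci)),
                    supporting_gene = rep(NA_character_, nrow(loci)),
                    overlap_nt = rep(0L, nrow(loci)),
                    stringsAsFactors = FALSE)
  if (nrow(loci) == 0L || nrow(genes) == 0L) return(out)

  ## 0-based half-open -> 1-based inclusive for GRanges
  common <- union(loci$chrom, genes$chrom)
  tg <- GenomicRanges::GRanges(factor(loci$chrom, levels = common),
                               IRanges::IRanges(loci$start + 1L, loci$end))
  gg <- GenomicRanges::GRanges(factor(genes$chrom, levels = common),
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(tg, gg, minoverlap = 1L,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  for (i in unique(qh)) {
    gi <- sh[qh == i]
    ov <- pmin(loci$end[i], genes$end[gi]) - pmax(loci$start[i], genes$start[gi])
    same <- genes$strand[gi] == loci$strand[i]
    use_same <- if (strand_precedence == "sense") any(same) else !any(!same)
    sel <- if (use_same) which(same) else which(!same)
    ## supporting gene: max overlap, tie -> smaller gene start
    ord <- sel[order(-ov[sel], genes$start[gi[sel]])]
    pick <- ord[1L]
    if (use_same) {
      contained <- genes$start[gi[sel]] <= loci$start[i] &
        genes$end[gi[sel]] >= loci$end[i]
      if (any(contained)) {
        cl <- "intragenic"
        ordc <- sel[contained][order(-ov[sel][contained],
                                     genes$start[gi[sel][contained]])]
        pick <- ordc[1L]
      } else {
        cl <- "overlapping"
      }
    } else {
      cl <- "antisense"
    }
    out$positional_class[i] <- cl
    out$supporting_gene[i] <- genes$gene_id[gi[pick]]
    out$overlap_nt[i] <- ov[pick]
  }
  out
}
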