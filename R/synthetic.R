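## Seeded synthetic dataset with planted ground truth for every pipeline
## stage.  Background sequence is i.i.d. uniform over {A,C,G,T}: at the
## pipeline's identity/coverage thresholds, spurious hits between
## unrelated uniform sequences are vanishingly rare, so the planted truth
## stays clean.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Random sequence whose longest forward-frame ORF stays below max_aa,
## by rejection sampling; keeps planted lncRNAs clear of both the ORF
## screen and the coding-potential heuristic.
rand_noncoding_seq <- function(len, max_aa = 40L, tries = 500L) {
  for (i in seq_len(tries)) {
    s <- rand_seq(len)
    orf <- find_longest_orf(s)
    if (is.null(orf) || orf$aa_length <= max_aa) return(s)
  }
  stop("generation error: could not draw a ", len,
       "-nt sequence with ORF <= ", max_aa, " AA in ", tries, " tries")
}

## 61 sense codons (no stop); used to write ORFs of a chosen length.
non_stop_codons <- function() {
  all3 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

orf_of_length <- function(aa) {
  paste0("ATG", paste(sample(non_stop_codons(), aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Produces a complete toy input set for the lncRNA identification
#' cascade -- genome, annotation, transcripts, counts, sRNA libraries,
#' miRNA precursor library, CDS set and tissue matrix -- together with a
#' per-transcript truth table recording what was planted.  All randomness
#' flows from `seed`; the same seed reproduces the dataset exactly.
#'
#' What is planted, by default:
#' * lncRNAs in each positional class, constructed geometrically
#'   (intergenic loci at least `gap` nt from any gene; intragenic and
#'   antisense loci inside a gene span on the same/opposite strand;
#'   overlapping loci crossing a gene boundary on the same strand);
#' * miRNA-precursor hosts carrying a verbatim embedded precursor copy;
#' * siRNA-precursor hosts with 21-24 nt reads sliced from both strands
#'   into the siRNA library; shRNA/siRNA hosts with slices in both
#'   libraries; `other` lncRNAs with no read support;
#' * antisense CDS partners built as the reverse complement of an lncRNA
#'   subrange plus short random flanks, so the lncRNA covers >90% of the
#'   CDS at 100% identity;
#' * treatment counts scaled by the true fold change with Poisson noise
#'   (default 4-fold up, 1/4 down for a minority, ~1:5 down:up);
#' * decoys exercising every filter: protein-coding transcripts (ORF >=
#'   100 AA), short transcripts (< 200 nt), long-ORF transcripts (80-99
#'   AA, still non-coding by span fraction) and unchanged transcripts
#'   (fold 1);
#' * a tissue matrix with single-tissue (tau = 1) and ubiquitous
#'   (tau = 0) profiles for the `other`-class lncRNAs.
#'
#' Library sizes (total mapped reads per condition) are nominal
#' full-library totals carried alongside the counts, reflecting that the
#' analyzed transcripts are a small subset of a real library.
#'
#' @param seed Integer RNG seed.
#' @param n_positional Named integer vector: planted lncRNAs per
#'   positional class.
#' @param n_precursor Named integer vector: planted lncRNAs per precursor
#'   class; must sum to `sum(n_positional)`.
#' @param n_cds_partners Number of `other`-class, non-antisense lncRNAs
#'   given a planted antisense CDS partner.
#' @param n_coding_decoys,n_short_decoys,n_longorf_decoys,n_unchanged_decoys
#'   Decoy counts (see above).
#' @param prop_down Fraction of planted lncRNAs downregulated.
#' @param true_fold Planted fold change for regulated transcripts.
#' @param base_mean Range of per-replicate mean control counts.
#' @param n_replicates Replicates per condition.
#' @param total_mapped Nominal library size per condition (total mapped
#'   reads).
#' @param lnc_length,gene_length,precursor_length Length ranges (nt).
#' @param reads_per_host Range of reads sliced per host and library.
#' @param read_length Range of sliced read lengths (nt).
#' @param n_decoy_reads Random unmatched reads added per library.
#' @param n_decoy_cds Random CDS sequences without a planted partner.
#' @param n_decoy_precursors Precursors in the library hosted by no
#'   lncRNA.
#' @param n_extra_genes Annotated genes with no planted transcript.
#' @param n_tissues Number of tissues in the expression matrix.
#' @param n_tissue_specific,n_tissue_ubiquitous How many `other`-class
#'   lncRNAs get a single-tissue / flat profile.
#' @param gap Minimum spacing (nt) between planted features.
#' @return An object of class `lnc_dataset`: list with `genome`,
#'   `annotation` (`genome_annotation`), `transcripts`, `loci`, `counts`
#'   (`count_table`), `total_mapped` (named vector), `precursors`,
#'   `reads` (data frame), `cds`, `tissue` (matrix), `truth` (data
#'   frame), `seed`.
#' @export
simulate_lnc_dataset <- function(
    seed = 1L,
    n_positional = c(intergenic = 30L, intragenic = 10L,
                     antisense = 4L, overlapping = 4L),
    n_precursor = c(miRNA_precursor = 3L, shRNA_siRNA_precursor = 6L,
                    siRNA_precursor = 15L, other = 24L),
    n_cds_partners = 4L,
    n_coding_decoys = 20L, n_short_decoys = 10L,
    n_longorf_decoys = 10L, n_unchanged_decoys = 12L,
    prop_down = 1 / 6, true_fold = 4,
    base_mean = c(150, 300), n_replicates = 2L, total_mapped = 1e6,
    lnc_length = c(300L, 800L), gene_length = c(2000L, 3000L),
    precursor_length = c(100L, 140L),
    reads_per_host = c(10L, 50L), read_length = c(21L, 24L),
    n_decoy_reads = 50L, n_decoy_cds = 26L, n_decoy_precursors = 3L,
    n_extra_genes = 5L, n_tissues = 9L,
    n_tissue_specific = 16L, n_tissue_ubiquitous = 8L,
    gap = 1000L) {

  stopifnot(sum(n_positional) == sum(n_precursor),
            all(n_positional >= 0L), all(n_precursor >= 0L))
  if (n_tissue_specific + n_tissue_ubiquitous > n_precursor[["other"]]) {
    stop("tissue profiles requested for more transcripts than the 'other' class holds")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n_lnc <- sum(n_positional)
  lnc_ids <- sprintf("lnc_%03d", seq_len(n_lnc))
  positional <- rep(names(n_positional), n_positional)
  precursor <- if (n_lnc > 0L) sample(rep(names(n_precursor), n_precursor)) else character()

  ## --- precursor library -------------------------------------------------
  n_mirna <- sum(precursor == "miRNA_precursor")
  n_prec_total <- n_mirna + n_decoy_precursors
  prec_ids <- sprintf("MIR%03d", seq_len(n_prec_total))
  precursors <- stats::setNames(vapply(seq_len(n_prec_total), function(i) {
    rand_seq(sample(precursor_length[1L]:precursor_length[2L], 1L))
  }, character(1L)), prec_ids)
  hosted_prec <- prec_ids[seq_len(n_mirna)]  # first n_mirna get hosts

  ## --- lncRNA sequences --------------------------------------------------
  lnc_seq <- character(n_lnc)
  mirna_host_of <- stats::setNames(rep(NA_character_, n_lnc), lnc_ids)
  mi_idx <- which(precursor == "miRNA_precursor")
  for (i in seq_len(n_lnc)) {
    len <- sample(lnc_length[1L]:lnc_length[2L], 1L)
    if (i %in% mi_idx) {
      p <- hosted_prec[match(i, mi_idx)]
      pseq <- precursors[[p]]
      len <- max(len, nchar(pseq) + 120L)
      ok <- FALSE
      for (try in 1:300) {
        host <- rand_seq(len - nchar(pseq))
        at <- sample.int(nchar(host) - 1L, 1L)
        cand <- paste0(substr(host, 1L, at), pseq,
                       substr(host, at + 1L, nchar(host)))
        orf <- find_longest_orf(cand)
        if (!is.null(orf) && orf$aa_length > 40L) next
        ## planted margin check: the embedded copy must clear the
        ## default miRNA gate (>99% identity, >90% precursor coverage)
        hit <- align_local(pseq, cand, query_id = p)
        if (hit$identity_pct > 99 && hit$query_cov_pct > 90) {
          lnc_seq[i] <- cand
          mirna_host_of[i] <- p
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("generation error: could not embed precursor ", p)
    } else {
      lnc_seq[i] <- rand_noncoding_seq(len)
    }
  }

  ## --- decoys ------------------------------------------------------------
  mk_coding <- function() {
    aa <- sample(100:140, 1L)
    orf <- orf_of_length(aa)
    paste0(rand_seq(sample(80:150, 1L)), orf, rand_seq(sample(80:150, 1L)))
  }
  mk_longorf <- function() {
    for (try in 1:300) {
      aa <- sample(82:95, 1L)
      span <- 3L * (aa + 1L)
      flank <- span + sample(60:150, 1L)
      s <- paste0(rand_noncoding_seq(ceiling(flank / 2), max_aa = 30L),
                  orf_of_length(aa),
                  rand_noncoding_seq(ceiling(flank / 2), max_aa = 30L))
      orf <- find_longest_orf(s)
      if (!is.null(orf) && orf$aa_length >= 80L && orf$aa_length < 100L &&
          coding_potential_score(s)$label == "noncoding") return(s)
    }
    stop("generation error: could not build long-ORF decoy")
  }
  coding_ids <- sprintf("decoy_coding_%02d", seq_len(n_coding_decoys))
  short_ids <- sprintf("decoy_short_%02d", seq_len(n_short_decoys))
  longorf_ids <- sprintf("decoy_longorf_%02d", seq_len(n_longorf_decoys))
  unch_ids <- sprintf("decoy_unchanged_%02d", seq_len(n_unchanged_decoys))
  decoy_seq <- c(
    stats::setNames(vapply(coding_ids, function(.) mk_coding(), character(1L)),
                    coding_ids),
    stats::setNames(vapply(short_ids, function(.)
      rand_noncoding_seq(sample(120:180, 1L), max_aa = 15L), character(1L)),
      short_ids),
    stats::setNames(vapply(longorf_ids, function(.) mk_longorf(), character(1L)),
                    longorf_ids),
    stats::setNames(vapply(unch_ids, function(.)
      rand_noncoding_seq(sample(lnc_length[1L]:lnc_length[2L], 1L)),
      character(1L)), unch_ids))

  transcripts <- c(stats::setNames(lnc_seq, lnc_ids), decoy_seq)
  all_ids <- names(transcripts)
  role <- c(rep("lncRNA", n_lnc),
            rep("coding_decoy", n_coding_decoys),
            rep("short_decoy", n_short_decoys),
            rep("longorf_decoy", n_longorf_decoys),
            rep("unchanged_decoy", n_unchanged_decoys))

  ## --- genomic placement -------------------------------------------------
  chroms <- c("chr1", "chr2")
  cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  pos_class_all <- c(positional, rep("intergenic", length(decoy_seq)))
  genes <- list()
  loci <- list()
  gi <- 0L
  for (k in seq_along(all_ids)) {
    chrom <- chroms[(k %% length(chroms)) + 1L]
    tlen <- nchar(transcripts[[k]])
    bs <- cursor[[chrom]] + gap
    cls <- pos_class_all[k]
    if (cls %in% c("intragenic", "antisense", "overlapping")) {
      gi <- gi + 1L
      gstrand <- sample(c("+", "-"), 1L)
      glen <- max(sample(gene_length[1L]:gene_length[2L], 1L), tlen + 400L)
      if (cls == "overlapping") {
        overhang <- 200L
        g0 <- bs + overhang
        tstart <- bs
        tend <- bs + tlen
        if (tend >= g0 + glen) stop("generation error: overlap placement infeasible")
        tstrand <- gstrand
      } else {
        g0 <- bs
        toff <- sample(50L:(glen - tlen - 50L), 1L)
        tstart <- g0 + toff
        tend <- tstart + tlen
        tstrand <- if (cls == "antisense")
          setdiff(c("+", "-"), gstrand) else gstrand
      }
      genes[[gi]] <- data.frame(gene_id = sprintf("gene_%03d", gi),
                                chrom = chrom, start = g0, end = g0 + glen,
                                strand = gstrand, biotype = "protein_coding",
                                stringsAsFactors = FALSE)
      cursor[[chrom]] <- max(g0 + glen, tend)
    } else {
      tstart <- bs
      tend <- bs + tlen
      tstrand <- sample(c("+", "-"), 1L)
      cursor[[chrom]] <- tend
    }
    loci[[k]] <- data.frame(id = all_ids[k], chrom = chrom,
                            start = tstart, end = tend, strand = tstrand,
                            stringsAsFactors = FALSE)
  }
  for (e in seq_len(n_extra_genes)) {
    chrom <- chroms[(e %% length(chroms)) + 1L]
    gi <- gi + 1L
    glen <- sample(gene_length[1L]:gene_length[2L], 1L)
    g0 <- cursor[[chrom]] + gap
    genes[[gi]] <- data.frame(gene_id = sprintf("gene_%03d", gi),
                              chrom = chrom, start = g0, end = g0 + glen,
                              strand = sample(c("+", "-"), 1L),
                              biotype = "protein_coding",
                              stringsAsFactors = FALSE)
    cursor[[chrom]] <- g0 + glen
  }
  genes <- do.call(rbind, genes)
  loci <- do.call(rbind, loci)

  ## genome: uniform background, with each transcript's sequence planted
  ## at its locus (reverse complement on the minus strand)
  genome <- stats::setNames(vapply(chroms, function(ch) {
    len <- cursor[[ch]] + 500L
    letters <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    sel <- which(loci$chrom == ch)
    for (k in sel) {
      s <- transcripts[[loci$id[k]]]
      if (loci$strand[k] == "-") s <- revcomp(s)
      letters[(loci$start[k] + 1L):loci$end[k]] <-
        strsplit(s, "", fixed = TRUE)[[1L]]
    }
    paste(letters, collapse = "")
  }, character(1L)), chroms)

  annotation <- structure(
    list(genes = genes,
         transcripts = stats::setNames(loci, c("id", "chrom", "start", "end", "strand"))),
    class = "genome_annotation")

  ## --- differential expression -------------------------------------------
  n_down <- round(prop_down * n_lnc)
  down_idx <- if (n_down > 0L) sample(seq_len(n_lnc), n_down) else integer()
  fold <- stats::setNames(rep(1, length(all_ids)), all_ids)
  fold[lnc_ids] <- true_fold
  fold[lnc_ids[down_idx]] <- 1 / true_fold
  fold[c(coding_ids, short_ids, longorf_ids)] <- true_fold
  fold[unch_ids] <- 1
  lambda <- stats::runif(length(all_ids), base_mean[1L], base_mean[2L])
  control <- t(vapply(lambda, function(l) stats::rpois(n_replicates, l),
                      integer(n_replicates)))
  treatment <- t(vapply(seq_along(lambda), function(i)
    stats::rpois(n_replicates, lambda[i] * fold[i]), integer(n_replicates)))
  counts <- structure(list(ids = all_ids, control = control,
                           treatment = treatment), class = "count_table")

  ## --- sRNA read libraries ------------------------------------------------
  read_rows <- list()
  slice_reads <- function(seq, n, lib, tag) {
    lapply(seq_len(n), function(j) {
      w <- sample(read_length[1L]:read_length[2L], 1L)
      off <- sample.int(nchar(seq) - w + 1L, 1L) - 1L
      r <- substr(seq, off + 1L, off + w)
      if (stats::runif(1) < 0.5) r <- revcomp(r)
      data.frame(read_id = sprintf("%s_%s_%02d", lib, tag, j),
                 sequence = r, library = lib, stringsAsFactors = FALSE)
    })
  }
  si_hosts <- lnc_ids[precursor == "siRNA_precursor"]
  shsi_hosts <- lnc_ids[precursor == "shRNA_siRNA_precursor"]
  for (id in si_hosts) {
    n <- sample(reads_per_host[1L]:reads_per_host[2L], 1L)
    read_rows <- c(read_rows, slice_reads(transcripts[[id]], n, "siRNA", id))
  }
  for (id in shsi_hosts) {
    for (lib in c("shRNA", "siRNA")) {
      n <- sample(reads_per_host[1L]:reads_per_host[2L], 1L)
      read_rows <- c(read_rows, slice_reads(transcripts[[id]], n, lib, id))
    }
  }
  for (lib in c("shRNA", "siRNA")) {
    read_rows <- c(read_rows, lapply(seq_len(n_decoy_reads), function(j) {
      data.frame(read_id = sprintf("%s_decoy_%03d", lib, j),
                 sequence = rand_seq(sample(read_length[1L]:read_length[2L], 1L)),
                 library = lib, stringsAsFactors = FALSE)
    }))
  }
  reads <- do.call(rbind, read_rows)
  rownames(reads) <- NULL

  ## --- CDS set ------------------------------------------------------------
  other_nonanti <- lnc_ids[precursor == "other" & positional != "antisense"]
  if (length(other_nonanti) < n_cds_partners) {
    stop("generation error: not enough non-antisense 'other' lncRNAs for CDS partners")
  }
  partner_hosts <- other_nonanti[seq_len(n_cds_partners)]
  cds_partner_of <- stats::setNames(rep(NA_character_, n_lnc), lnc_ids)
  cds <- character()
  for (j in seq_along(partner_hosts)) {
    id <- partner_hosts[j]
    seq <- transcripts[[id]]
    repeat {
      m <- min(300L, nchar(seq) - 20L)
      st <- sample.int(nchar(seq) - m + 1L, 1L)
      sub <- substr(seq, st, st + m - 1L)
      cand <- paste0(rand_seq(10L), revcomp(sub), rand_seq(10L))
      hit <- align_local(seq, cand, orientation = "plus/minus")
      cov <- max(hit$query_cov_pct, hit$subject_cov_pct)
      if (hit$identity_pct > 90 && cov > 90) break
    }
    cid <- sprintf("cds_partner_%02d", j)
    cds[cid] <- cand
    cds_partner_of[id] <- cid
  }
  for (j in seq_len(n_decoy_cds)) {
    cds[sprintf("cds_decoy_%02d", j)] <- rand_seq(sample(300:900, 1L))
  }

  ## --- tissue matrix ------------------------------------------------------
  tissue_names <- c("whole_seed", "anthers", "husk", "cob", "silks",
                    "primary_root", "pooled_leaves", "topmost_leaf",
                    "stem_sam")[seq_len(n_tissues)]
  other_ids <- lnc_ids[precursor == "other"]
  spec_ids <- other_ids[seq_len(n_tissue_specific)]
  ubiq_ids <- other_ids[n_tissue_specific + seq_len(n_tissue_ubiquitous)]
  tissue <- matrix(0, nrow = length(spec_ids) + length(ubiq_ids),
                   ncol = n_tissues,
                   dimnames = list(c(spec_ids, ubiq_ids), tissue_names))
  specific_tissue <- stats::setNames(rep(NA_character_, n_lnc), lnc_ids)
  for (id in spec_ids) {
    tix <- sample.int(n_tissues, 1L)
    tissue[id, tix] <- stats::runif(1, 50, 200)
    specific_tissue[id] <- tissue_names[tix]
  }
  for (id in ubiq_ids) tissue[id, ] <- stats::runif(1, 20, 60)

  ## --- truth table --------------------------------------------------------
  de_direction <- ifelse(fold >= 2, "up", ifelse(fold <= 0.5, "down", "unchanged"))
  truth <- data.frame(
    id = all_ids, role = role,
    positional_class = pos_class_all,
    precursor_class = c(precursor, rep(NA_character_, length(decoy_seq))),
    de_direction = unname(de_direction),
    true_fold = unname(fold),
    mirna_precursor = c(unname(mirna_host_of), rep(NA_character_, length(decoy_seq))),
    cds_partner = c(unname(cds_partner_of), rep(NA_character_, length(decoy_seq))),
    specific_tissue = c(unname(specific_tissue), rep(NA_character_, length(decoy_seq))),
    stringsAsFactors = FALSE)

  structure(list(genome = genome, annotation = annotation,
                 transcripts = transcripts, loci = loci, counts = counts,
                 total_mapped = c(control = total_mapped, treatment = total_mapped),
                 precursors = precursors, reads = reads, cds = cds,
                 tissue = tissue, truth = truth, seed = seed),
            class = "lnc_dataset")
}

#' @export
print.lnc_dataset <- function(x, ...) {
  cat("synthetic lncRNA screening dataset (seed ", x$seed, ")\n", sep = "")
  cat("  transcripts:", length(x$transcripts),
      "(", sum(x$truth$role == "lncRNA"), "planted lncRNAs )\n")
  cat("  genes:", nrow(x$annotation$genes), "on",
      length(x$genome), "chromosomes\n")
  cat("  sRNA reads:", nrow(x$reads), " CDS:", length(x$cds),
      " precursors:", length(x$precursors), "\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory of standard files
#'
#' Emits exactly the formats the pipeline consumes: `genome.fa`,
#' `annotation.gff3` (genes + transcript loci), `transcripts.fa`,
#' `counts.tsv`, `library_sizes.tsv`, `mirna_precursors.fa`,
#' `srna_shRNA.fa`, `srna_siRNA.fa`, `cds.fa`, `tissue.tsv` and
#' `truth.tsv`.
#'
#' @param dataset An `lnc_dataset` (see [simulate_lnc_dataset()]).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_lnc_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lnc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(dataset$genome, p("genome.fa"))
  write_gff3(dataset$annotation, p("annotation.gff3"))
  write_fasta(dataset$transcripts, p("transcripts.fa"))
  write_counts(dataset$counts, p("counts.tsv"))
  utils::write.table(
    data.frame(condition = names(dataset$total_mapped),
               total_mapped = as.integer(dataset$total_mapped)),
    p("library_sizes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(dataset$precursors, p("mirna_precursors.fa"))
  for (lib in unique(dataset$reads$library)) {
    sel <- dataset$reads$library == lib
    write_fasta(stats::setNames(dataset$reads$sequence[sel],
                                dataset$reads$read_id[sel]),
                p(sprintf("srna_%s.fa", lib)))
  }
  write_fasta(dataset$cds, p("cds.fa"))
  tis <- data.frame(id = rownames(dataset$tissue), dataset$tissue,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tis, p("tissue.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

#' Read a dataset directory written by [write_lnc_dataset()]
#'
#' @param dir Directory containing the standard files.
#' @return An `lnc_dataset` object (without the `genome` unless
#'   `genome.fa` is present; `truth` is included when `truth.tsv` is
#'   present).
#' @export
read_lnc_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  annotation <- read_gff3(p("annotation.gff3"))
  transcripts <- read_fasta(p("transcripts.fa"))
  loci <- annotation$transcripts
  counts <- read_counts(p("counts.tsv"))
  total_mapped <- NULL
  if (file.exists(p("library_sizes.tsv"))) {
    ls <- utils::read.delim(p("library_sizes.tsv"), stringsAsFactors = FALSE)
    total_mapped <- stats::setNames(ls$total_mapped, ls$condition)
  }
  reads <- do.call(rbind, lapply(c("shRNA", "siRNA"), function(lib) {
    f <- p(sprintf("srna_%s.fa", lib))
    if (!file.exists(f)) return(NULL)
    v <- read_fasta(f)
    data.frame(read_id = names(v), sequence = unname(v), library = lib,
               stringsAsFactors = FALSE)
  }))
  tissue <- NULL
  if (file.exists(p("tissue.tsv"))) {
    tis <- utils::read.delim(p("tissue.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
    tissue <- as.matrix(tis[, -1L, drop = FALSE])
    rownames(tissue) <- tis[[1L]]
  }
  truth <- if (file.exists(p("truth.tsv")))
    utils::read.delim(p("truth.tsv"), stringsAsFactors = FALSE) else NULL
  genome <- if (file.exists(p("genome.fa"))) read_fasta(p("genome.fa")) else NULL
  structure(list(genome = genome, annotation = annotation,
                 transcripts = transcripts, loci = loci, counts = counts,
                 total_mapped = total_mapped,
                 precursors = read_fasta(p("mirna_precursors.fa")),
                 reads = reads, cds = read_fasta(p("cds.fa")),
                 tissue = tissue, truth = truth, seed = NA_integer_),
            class = "lnc_dataset")
}
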