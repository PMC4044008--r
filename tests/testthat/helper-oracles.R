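# Independent reference implementations used to cross-check the package:
# brute-force enumeration / naive full-matrix routines kept deliberately
# separate from the code paths they verify.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Longest forward-frame ORF by direct enumeration of every ATG.
orf_oracle <- function(s) {
  n <- nchar(s)
  best <- NULL
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(s, i, i + 2L) == "ATG") {
      j <- i + 3L
      aa <- 1L
      while (j + 2L <= n) {
        cod <- substr(s, j, j + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (is.null(best) || aa > best$aa_length ||
              (aa == best$aa_length && (i - 1L) < best$start_nt)) {
            best <- list(frame = (i - 1L) %% 3L, start_nt = i - 1L,
                         aa_length = aa, has_stop = TRUE)
          }
          break
        }
        aa <- aa + 1L
        j <- j + 3L
      }
    }
  }
  best
}

# Step-up BH by direct enumeration of all cutoffs.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    vals <- vapply(k:m, function(j) m * p[o[j]] / j, numeric(1L))
    adj[o[k]] <- min(1, vals)
  }
  adj
}

# Naive full-matrix Gotoh local-alignment optimal score (no traceback).
sw_oracle <- function(q, s, match = 2, mismatch = -3, open = -5, ext = -2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(qc)
  m <- length(sc)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] + open, E[i, j - 1L] + ext)
      F[i, j] <- max(H[i - 1L, j] + open, F[i - 1L, j] + ext)
      sub <- if (qc[i - 1L] == sc[j - 1L] && qc[i - 1L] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Sliding-window exact-substring scan: 0-based offsets of read in seq.
scan_oracle <- function(read, seq) {
  w <- nchar(read)
  n <- nchar(seq)
  if (w > n) return(integer())
  which(vapply(seq_len(n - w + 1L),
               function(i) substr(seq, i, i + w - 1L) == read,
               logical(1L))) - 1L
}

# Positional class by testing every (transcript, gene) pair directly.
position_oracle <- function(tstart, tend, tstrand, tchrom, genes) {
  onchrom <- genes$chrom == tchrom
  ov <- pmin(tend, genes$end) - pmax(tstart, genes$start)
  hit <- which(onchrom & ov > 0)
  if (!length(hit)) return("intergenic")
  same <- hit[genes$strand[hit] == tstrand]
  if (length(same)) {
    if (any(genes$start[same] <= tstart & genes$end[same] >= tend)) {
      "intragenic"
    } else {
      "overlapping"
    }
  } else {
    "antisense"
  }
}

# Small random gene annotation on two chromosomes.
random_annotation <- function(n_genes, span = 10000L) {
  starts <- sample.int(span, n_genes, replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
             chrom = sample(c("chrA", "chrB"), n_genes, replace = TRUE),
             start = starts,
             end = starts + sample(100:2000, n_genes, replace = TRUE),
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             biotype = "protein_coding",
             stringsAsFactors = FALSE)
}

# Point-mutate k positions of a sequence (guaranteed base change).
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}
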