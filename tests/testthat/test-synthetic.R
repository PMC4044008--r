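# A reduced generator profile keeps unit tests fast; the full default
# profile is exercised in the end-to-end acceptance tests.
small_spec <- function(seed) {
  simulate_lnc_dataset(
    seed = seed,
    n_positional = c(intergenic = 6L, intragenic = 3L,
                     antisense = 2L, overlapping = 2L),
    n_precursor = c(miRNA_precursor = 1L, shRNA_siRNA_precursor = 2L,
                    siRNA_precursor = 4L, other = 6L),
    n_cds_partners = 2L,
    n_coding_decoys = 3L, n_short_decoys = 2L, n_longorf_decoys = 2L,
    n_unchanged_decoys = 3L,
    n_decoy_reads = 10L, n_decoy_cds = 4L, n_decoy_precursors = 1L,
    n_extra_genes = 2L, n_tissue_specific = 4L, n_tissue_ubiquitous = 2L)
}

test_that("the same seed reproduces the dataset byte-for-byte", {
  d1 <- small_spec(5)
  d2 <- small_spec(5)
  expect_identical(d1, d2)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_lnc_dataset(d1, dir1)
  write_lnc_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  d3 <- small_spec(6)
  expect_false(identical(d1$transcripts, d3$transcripts))
})

test_that("every transcript has exactly one truth record and a locus", {
  d <- small_spec(7)
  expect_setequal(d$truth$id, names(d$transcripts))
  expect_equal(anyDuplicated(d$truth$id), 0L)
  expect_setequal(d$loci$id, names(d$transcripts))
  # planted loci carry the transcript sequence in the genome
  for (k in sample(nrow(d$loci), 5)) {
    chrom_seq <- d$genome[[d$loci$chrom[k]]]
    piece <- substr(chrom_seq, d$loci$start[k] + 1L, d$loci$end[k])
    s <- d$transcripts[[d$loci$id[k]]]
    if (d$loci$strand[k] == "-") s <- revcomp(s)
    expect_identical(piece, s)
  }
})

test_that("planted structural constraints hold", {
  d <- small_spec(8)
  lnc <- d$truth[d$truth$role == "lncRNA", ]
  # lncRNAs are all >200 nt with sub-threshold ORFs
  lens <- nchar(d$transcripts[lnc$id])
  expect_true(all(lens > 200))
  # shRNA/siRNA hosts have support in both libraries; 'other' in none
  m <- match_reads_exact(d$transcripts[lnc$id], d$reads)
  for (id in lnc$id[lnc$precursor_class == "shRNA_siRNA_precursor"]) {
    libs <- m$support$library[m$support$lncrna_id == id]
    expect_setequal(libs, c("shRNA", "siRNA"))
  }
  expect_false(any(m$support$lncrna_id %in%
                   lnc$id[lnc$precursor_class == "other"]))
  # read lengths within the sliced range
  expect_true(all(nchar(d$reads$sequence) >= 21 &
                  nchar(d$reads$sequence) <= 24))
})

test_that("a dataset round-trips through its file representation", {
  d <- small_spec(9)
  dir <- withr::local_tempdir()
  write_lnc_dataset(d, dir)
  back <- read_lnc_dataset(dir)
  expect_identical(back$transcripts, d$transcripts)
  expect_identical(unname(back$counts$control), unname(d$counts$control))
  expect_equal(back$annotation$genes$start, d$annotation$genes$start)
  expect_identical(sort(back$reads$read_id), sort(d$reads$read_id))
  expect_equal(unname(back$tissue), unname(d$tissue))
  expect_identical(back$truth$precursor_class, d$truth$precursor_class)
})

test_that("degrading a planted precursor copy below the identity gate flips the call", {
  set.seed(113)
  d <- small_spec(10)
  host_row <- which(!is.na(d$truth$mirna_precursor))[1]
  host_id <- d$truth$id[host_row]
  prec_id <- d$truth$mirna_precursor[host_row]
  lnc <- d$transcripts[host_id]
  expect_equal(nrow(classify_mirna_precursor(lnc, d$precursors[prec_id])), 1)

  # mutate ~3% of the embedded copy: identity drops below 99%
  prec <- d$precursors[[prec_id]]
  at <- regexpr(prec, lnc[[1]], fixed = TRUE)
  expect_gt(at, 0)
  degraded <- lnc[[1]]
  substr(degraded, at, at + nchar(prec) - 1L) <-
    mutate_seq(prec, ceiling(0.03 * nchar(prec)))
  calls <- classify_mirna_precursor(setNames(degraded, host_id),
                                    d$precursors[prec_id])
  expect_equal(nrow(calls), 0)
})
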