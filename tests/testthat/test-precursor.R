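test_that("embedded precursor copies are called; diverged ones are not", {
  set.seed(71)
  prec <- setNames(rand_dna(120), "MIR001")
  host <- paste0(rand_dna(200), prec, rand_dna(200))
  lnc <- c(host = host, plain = rand_dna(500))
  calls <- classify_mirna_precursor(lnc, prec)
  expect_equal(calls$lncrna_id, "host")
  expect_equal(calls$precursor_id, "MIR001")
  expect_equal(calls$identity_pct, 100)
  expect_gte(calls$coverage_pct, 100)

  # ~80% identity: fails the >99% gate
  diverged <- paste0(rand_dna(200), mutate_seq(prec[[1]], 24), rand_dna(200))
  expect_equal(nrow(classify_mirna_precursor(c(d = diverged), prec)), 0)

  # embedded on the minus strand: found through plus/minus orientation
  rc_host <- paste0(rand_dna(150), revcomp(prec[[1]]), rand_dna(150))
  rc_calls <- classify_mirna_precursor(c(rc = rc_host), prec)
  expect_equal(rc_calls$orientation, "plus/minus")
  expect_equal(rc_calls$identity_pct, 100)

  expect_error(classify_mirna_precursor(lnc, character()), "empty")
})

test_that("one precursor may be shared and one lncRNA may host several", {
  set.seed(73)
  p1 <- rand_dna(110)
  p2 <- rand_dna(110)
  lib <- c(MIRa = p1, MIRb = p2)
  shared1 <- paste0(rand_dna(100), p1, rand_dna(100))
  shared2 <- paste0(rand_dna(80), p1, rand_dna(150))
  double <- paste0(rand_dna(50), p1, rand_dna(60), p2, rand_dna(50))
  calls <- classify_mirna_precursor(c(a = shared1, b = shared2, c = double), lib)
  expect_equal(sum(calls$precursor_id == "MIRa"), 3)
  expect_setequal(calls$precursor_id[calls$lncrna_id == "c"], c("MIRa", "MIRb"))
})

test_that("exact read matching records offsets on both strands", {
  set.seed(79)
  lnc <- c(L1 = rand_dna(300))
  sense_read <- substr(lnc[["L1"]], 41, 61)          # offset 40, 21 nt
  anti_read <- revcomp(substr(lnc[["L1"]], 101, 124)) # offset 100, 24 nt
  reads <- data.frame(read_id = c("r1", "r2", "r3"),
                      sequence = c(sense_read, anti_read, rand_dna(22)),
                      library = c("siRNA", "siRNA", "siRNA"),
                      stringsAsFactors = FALSE)
  m <- match_reads_exact(lnc, reads)
  r1 <- m$positions[m$positions$read_id == "r1", ]
  expect_equal(r1$offset, 40L)
  expect_equal(r1$strand, "sense")
  r2 <- m$positions[m$positions$read_id == "r2", ]
  expect_equal(r2$offset, 100L)
  expect_equal(r2$strand, "antisense")
  expect_false("r3" %in% m$positions$read_id)
  expect_equal(m$support$distinct_reads, 2L)

  # one mismatch to every substring: no support (zero-mismatch contract)
  mm <- mutate_seq(sense_read, 1)
  m2 <- match_reads_exact(lnc, data.frame(read_id = "m", sequence = mm,
                                          library = "siRNA",
                                          stringsAsFactors = FALSE))
  expect_equal(nrow(m2$positions), 0)

  # sense-only mode drops the antisense hit
  m3 <- match_reads_exact(lnc, reads, both_strands = FALSE)
  expect_false("r2" %in% m3$positions$read_id)

  expect_error(match_reads_exact(lnc, data.frame(read_id = "x",
                                                 sequence = rand_dna(10),
                                                 library = "siRNA")),
               "length")
})

test_that("read occurrences equal the sliding-window scan oracle", {
  set.seed(83)
  for (case in 1:40) {
    lnc <- rand_dna(sample(80:200, 1))
    w <- sample(18:24, 1)
    reads <- c(
      substr(lnc, 5, 4 + w),                       # planted sense
      revcomp(substr(lnc, 31, 30 + w)),            # planted antisense
      rand_dna(w)                                  # random
    )
    df <- data.frame(read_id = sprintf("r%d", seq_along(reads)),
                     sequence = reads, library = "siRNA",
                     stringsAsFactors = FALSE)
    m <- match_reads_exact(c(x = lnc), df)
    for (k in seq_along(reads)) {
      got_s <- sort(m$positions$offset[m$positions$read_id == df$read_id[k] &
                                       m$positions$strand == "sense"])
      got_a <- sort(m$positions$offset[m$positions$read_id == df$read_id[k] &
                                       m$positions$strand == "antisense"])
      exp_s <- sort(scan_oracle(reads[k], lnc))
      # antisense oracle: the reverse complement of the read occurs on
      # the sense strand; offsets are reported in sense coordinates
      exp_a <- sort(scan_oracle(revcomp(reads[k]), lnc))
      expect_equal(got_s, exp_s)
      expect_equal(got_a, exp_a)
    }
  }
})

test_that("hierarchy is precedence-ordered and partitions the cohort", {
  mirna_calls <- data.frame(lncrna_id = "m1", precursor_id = "MIRx",
                            stringsAsFactors = FALSE)
  support <- data.frame(
    lncrna_id = c("m1", "both", "both", "si_only", "sh_only"),
    library = c("siRNA", "shRNA", "siRNA", "siRNA", "shRNA"),
    distinct_reads = c(12L, 4L, 9L, 7L, 3L),
    stringsAsFactors = FALSE)
  ids <- c("m1", "both", "si_only", "sh_only", "nothing")
  got <- hierarchical_classify(ids, mirna_calls, support)
  expect_equal(got$precursor_class,
               c("miRNA_precursor",        # miRNA wins over read support
                 "shRNA_siRNA_precursor",
                 "siRNA_precursor",
                 "other",                  # no shRNA-only class exists
                 "other"))
  expect_true(got$shrna_only[got$id == "sh_only"])
  expect_false(any(got$shrna_only[got$id != "sh_only"]))
  expect_equal(nrow(got), length(ids))     # partition: one label each

  # min_reads gate
  got2 <- hierarchical_classify(ids, mirna_calls, support, min_reads = 5L)
  expect_equal(got2$precursor_class[got2$id == "both"], "siRNA_precursor")
})
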