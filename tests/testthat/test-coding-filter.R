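test_that("find_longest_orf counts Met, excludes stop, breaks ties deterministically", {
  orf <- find_longest_orf("ATGAAATAA")
  expect_equal(orf$aa_length, 2L)        # Met, Lys
  expect_equal(orf$start_nt, 0L)
  expect_equal(orf$frame, 0L)
  expect_true(orf$has_stop)

  expect_null(find_longest_orf("CCCCCC"))          # no ATG
  expect_null(find_longest_orf("ATGAAAAAA"))       # ATG without in-frame stop
  expect_null(find_longest_orf("ATNAAATAA"))       # N blocks the ATG codon

  # equal-length ORFs in frames 1 and 0: smaller start wins
  two <- find_longest_orf(paste0("ATGAAATAA", "C", "ATGAAATAA"))
  expect_equal(two$start_nt, 0L)
})

test_that("find_longest_orf agrees with exhaustive enumeration", {
  # all sequences of length 6-9 over {A,T,G}: dense in ATG/stop motifs
  alph <- c("A", "T", "G")
  for (len in 6:9) {
    grid <- do.call(expand.grid, c(rep(list(alph), len),
                                   stringsAsFactors = FALSE))
    seqs <- do.call(paste0, grid)
    set.seed(len)
    seqs <- seqs[sample(length(seqs), min(1500L, length(seqs)))]
    for (s in seqs) {
      got <- find_longest_orf(s)
      exp <- orf_oracle(s)
      expect_identical(got, exp, info = s)
    }
  }
  # long random sequences
  set.seed(31)
  for (i in 1:100) {
    s <- rand_dna(500)
    got <- find_longest_orf(s)
    exp <- orf_oracle(s)
    expect_identical(got, exp)
  }
})

test_that("truncating whole codons from the 3' end never lengthens the ORF", {
  set.seed(37)
  for (i in 1:25) {
    s <- rand_dna(402)
    full <- find_longest_orf(s)
    shorter <- find_longest_orf(substr(s, 1, nchar(s) - 9))
    full_aa <- if (is.null(full)) 0L else full$aa_length
    short_aa <- if (is.null(shorter)) 0L else shorter$aa_length
    expect_lte(short_aa, full_aa)
  }
})

test_that("coding-potential heuristic uses span fraction and ORF length", {
  # 89-AA ORF spans 270 nt of a 300-nt transcript -> coding by fraction
  s <- paste0(rand_dna(15), "ATG",
              paste(rep("GCT", 88), collapse = ""), "TAA", rand_dna(15))
  expect_equal(nchar(s), 300)
  expect_equal(coding_potential_score(s)$label, "coding")

  expect_equal(coding_potential_score("CCCCCCCCCC")$label, "noncoding")

  # >=100 AA is coding regardless of fraction
  long <- paste0(rand_dna(400), "ATG",
                 paste(rep("GCT", 100), collapse = ""), "TAA", rand_dna(400))
  expect_equal(coding_potential_score(long)$label, "coding")
})

test_that("length/ORF filter applies strict boundaries", {
  set.seed(41)
  # length 201, no ORF: retained (boundary is strict, > 200 nt)
  at_boundary <- paste(rep("C", 201), collapse = "")
  expect_equal(names(filter_lncrna_candidates(c(x = at_boundary))), "x")

  # length 200 exactly, no ORF: removed by the length gate
  short <- paste(rep("C", 200), collapse = "")
  expect_length(filter_lncrna_candidates(c(s = short)), 0)

  # 79-AA ORF: retained (boundary is strict, < 80 AA)
  pass <- paste0("ATG", paste(rep("GCT", 78), collapse = ""), "TAA")
  pass <- paste0(pass, paste(rep("C", 300), collapse = ""))
  keep <- filter_lncrna_candidates(c(y = pass),
                                   coding_labels = c(y = "noncoding"))
  expect_equal(names(keep), "y")

  # 80-AA ORF: removed by the ORF gate
  fail <- paste0("ATG", paste(rep("GCT", 79), collapse = ""), "TAA")
  fail <- paste0(fail, paste(rep("C", 300), collapse = ""))
  expect_length(filter_lncrna_candidates(c(f = fail),
                                         coding_labels = c(f = "noncoding")), 0)
})

test_that("external coding labels override the heuristic verbatim", {
  noorf <- paste(rep("C", 300), collapse = "")
  # heuristic would keep it; external 'coding' label removes it
  expect_length(filter_lncrna_candidates(c(x = noorf),
                                         coding_labels = c(x = "coding")), 0)
  expect_length(filter_lncrna_candidates(c(x = noorf)), 1)
})

test_that("filter is idempotent, order-invariant and recovers planted sets", {
  set.seed(43)
  passers <- setNames(replicate(10, {
    repeat {
      s <- rand_dna(sample(250:500, 1))
      o <- find_longest_orf(s)
      if ((is.null(o) || o$aa_length < 50) &&
          coding_potential_score(s)$label == "noncoding") break
    }
    s
  }), sprintf("pass_%02d", 1:10))
  failers <- setNames(c(
    replicate(5, rand_dna(sample(100:190, 1))),                 # too short
    replicate(5, paste0(rand_dna(300), "ATG",
                        paste(rep("GCT", 120), collapse = ""), "TAA",
                        rand_dna(300)))                          # long ORF
  ), sprintf("fail_%02d", 1:10))
  all20 <- c(passers, failers)
  kept <- filter_lncrna_candidates(all20)
  expect_setequal(names(kept), names(passers))
  expect_identical(filter_lncrna_candidates(kept), kept)           # idempotent
  shuffled <- all20[sample(length(all20))]
  expect_setequal(names(filter_lncrna_candidates(shuffled)), names(passers))
})
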