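mk_loci <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[[1]], chrom = r[[2]], start = as.integer(r[[3]]),
               end = as.integer(r[[4]]), strand = r[[5]],
               stringsAsFactors = FALSE)))
}

one_gene <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                       end = 500L, strand = "+", biotype = "protein_coding",
                       stringsAsFactors = FALSE)

test_that("positional cascade assigns the four classes", {
  loci <- mk_loci(list("empty_chrom", "chr9", 0, 100, "+"),
                  list("inside_same", "chr1", 150, 250, "+"),
                  list("inside_opp", "chr1", 150, 250, "-"),
                  list("crossing", "chr1", 450, 600, "+"),
                  list("far_away", "chr1", 5000, 5400, "-"))
  got <- classify_position(loci, one_gene)
  expect_equal(got$positional_class,
               c("intergenic", "intragenic", "antisense", "overlapping",
                 "intergenic"))
  expect_equal(got$supporting_gene,
               c(NA, "g1", "g1", "g1", NA))
  expect_equal(got$overlap_nt, c(0L, 100L, 100L, 50L, 0L))
})

test_that("same-strand evidence outranks opposite-strand by default", {
  genes <- rbind(one_gene,
                 data.frame(gene_id = "g2", chrom = "chr1", start = 120L,
                            end = 480L, strand = "-",
                            biotype = "protein_coding",
                            stringsAsFactors = FALSE))
  loci <- mk_loci(list("t", "chr1", 150, 250, "+"))
  expect_equal(classify_position(loci, genes)$positional_class, "intragenic")
  expect_equal(classify_position(loci, genes,
                                 strand_precedence = "antisense")$positional_class,
               "antisense")
})

test_that("malformed intervals are rejected", {
  expect_error(classify_position(mk_loci(list("t", "chr1", 200, 200, "+")),
                                 one_gene), "malformed")
})

test_that("classification equals the brute-force pair oracle", {
  set.seed(53)
  for (rep in 1:20) {
    genes <- random_annotation(sample(5:50, 1))
    n <- 40
    starts <- sample.int(12000L, n, replace = TRUE)
    loci <- data.frame(id = sprintf("t%02d", 1:n),
                       chrom = sample(c("chrA", "chrB", "chrC"), n, TRUE),
                       start = starts,
                       end = starts + sample(100:1500, n, TRUE),
                       strand = sample(c("+", "-"), n, TRUE),
                       stringsAsFactors = FALSE)
    got <- classify_position(loci, genes)
    exp <- vapply(seq_len(n), function(i)
      position_oracle(loci$start[i], loci$end[i], loci$strand[i],
                      loci$chrom[i], genes), character(1))
    expect_equal(got$positional_class, exp)
  }
})

test_that("labels partition the set and are translation invariant", {
  set.seed(59)
  genes <- random_annotation(30)
  n <- 50
  starts <- sample.int(12000L, n, replace = TRUE)
  loci <- data.frame(id = sprintf("t%02d", 1:n),
                     chrom = sample(c("chrA", "chrB"), n, TRUE),
                     start = starts, end = starts + sample(100:1500, n, TRUE),
                     strand = sample(c("+", "-"), n, TRUE),
                     stringsAsFactors = FALSE)
  got <- classify_position(loci, genes)
  expect_equal(nrow(got), n)  # exactly one label each
  expect_true(all(got$positional_class %in%
                  c("intergenic", "intragenic", "antisense", "overlapping")))
  expect_true(all(got$overlap_nt[got$positional_class != "intergenic"] > 0))
  expect_true(all(is.na(got$supporting_gene) ==
                  (got$positional_class == "intergenic")))

  shift <- 7777L
  loci2 <- transform(loci, start = start + shift, end = end + shift)
  genes2 <- transform(genes, start = start + shift, end = end + shift)
  expect_equal(classify_position(loci2, genes2)$positional_class,
               got$positional_class)
})
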