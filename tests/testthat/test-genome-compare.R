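test_that("substitution counting skips gap and ambiguous columns", {
  expect_equal(count_substitutions("ACGT", "ACGA"), 1)
  expect_equal(count_substitutions("AC-T", "ACGT"), 0)
  expect_equal(count_substitutions("ANGT", "ACGT"), 0)
  expect_equal(count_substitutions("ACGT", "ACGT"), 0)
  expect_error(count_substitutions("ACG", "ACGT"), "equal")
})

test_that("indel counting distinguishes gap positions from gap blocks", {
  expect_equal(count_indels("A--T", "ACGT", model = "indel"), 2)
  expect_equal(count_indels("A--T", "ACGT", model = "indelblock"), 1)
  expect_equal(count_indels("ACGT", "ACGT", model = "indel"), 0)
  expect_equal(count_indels("ACGT", "ACGT", model = "indelblock"), 0)
  # shared gap columns belong to neither sequence's indels
  expect_equal(count_indels("A-GT", "A-GT", model = "indel"), 0)
  # indelblock is never larger than indel
  expect_lte(count_indels("A--T-G", "ACGTAG", model = "indelblock"),
             count_indels("A--T-G", "ACGTAG", model = "indel"))
})

test_that("distance measures are symmetric in argument order", {
  set.seed(11)
  for (i in 1:20) {
    n <- 60
    a <- paste(sample(c("A", "C", "G", "T", "-"), n, TRUE,
                      prob = c(.22, .22, .22, .22, .12)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), n, TRUE,
                      prob = c(.22, .22, .22, .22, .12)), collapse = "")
    expect_identical(count_substitutions(a, b), count_substitutions(b, a))
    expect_identical(count_indels(a, b, "indel"), count_indels(b, a, "indel"))
    expect_identical(count_indels(a, b, "indelblock"),
                     count_indels(b, a, "indelblock"))
  }
})

test_that("inverted repeat detection recovers a planted IR pair", {
  set.seed(5)
  ir <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  g <- paste0(
    paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""),
    ir,
    paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""),
    revcomp(ir)
  )
  b <- find_inverted_repeats(g, min_ir = 1000)
  expect_setequal(b$region, c("LSC", "SSC", "IRa", "IRb"))
  expect_equal(b$length[b$region == "IRb"], 1200)
  expect_equal(b$length[b$region == "IRa"], 1200)
  expect_equal(b$length[b$region == "LSC"], 3000)
  expect_equal(b$length[b$region == "SSC"], 1500)
  # the two repeats are exact reverse complements
  irb <- b[b$region == "IRb", ]
  ira <- b[b$region == "IRa", ]
  expect_identical(substr(g, irb$start, irb$end),
                   revcomp(substr(g, ira$start, ira$end)))
})

test_that("a repeat-free sequence reports single-copy-only structure", {
  set.seed(6)
  g <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  b <- find_inverted_repeats(g, min_ir = 1000)
  expect_identical(b$region, "single-copy")
  expect_equal(b$length, 5000)
})

test_that("pairwise distance table covers all genome pairs symmetrically", {
  aln <- c(g1 = "ACGTACGT", g2 = "ACGAAC-T", g3 = "ACGTACGT")
  d <- plastome_distances(aln)
  expect_equal(nrow(d), 3)
  expect_equal(d$substitutions[d$genome1 == "g1" & d$genome2 == "g2"], 1)
  expect_equal(d$indelblock[d$genome1 == "g2" & d$genome2 == "g3"], 1)
  expect_equal(d$substitutions[d$genome1 == "g1" & d$genome2 == "g3"], 0)
})
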