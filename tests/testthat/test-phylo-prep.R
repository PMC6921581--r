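test_that("IRa removal drops exactly the repeat columns", {
  aln <- c(ref = strrep("A", 30), other = strrep("C", 30))
  out <- remove_ira(aln, 10, 20, reference = "ref")
  expect_equal(nchar(out$alignment[["ref"]]), 19)
  expect_equal(out$removed, c(10, 20))
  # alignment fully outside IRa is unchanged apart from those columns
  expect_identical(out$alignment[["other"]], strrep("C", 19))
  expect_error(remove_ira(aln, NA, 20), "boundaries")
})

test_that("homopolymer masking obeys the run-length threshold", {
  aln <- c(a = "GGAAAAAAGG", b = "GGAAAAAAGG")   # A x 6
  m <- mask_homopolymers(aln)
  expect_equal(m$mask$column, 3:8)
  aln5 <- c(a = "GGAAAAAGGC", b = "GGAAAAAGGC")  # A x 5: below threshold
  expect_equal(nrow(mask_homopolymers(aln5)$mask), 0)
})

test_that("runs inside annotated CDS are not masked", {
  aln <- c(a = "GGAAAAAAGG", b = "GGAAAAAAGG")
  m <- mask_homopolymers(aln, cds = tibble::tibble(start = 1, end = 10),
                         reference = "a")
  expect_equal(nrow(m$mask), 0)
})

test_that("masking is reconstructable: mask + output rebuild the input", {
  aln <- c(a = "GGAAAAAAGGTT-CC", b = "GGAAAAAAGGTTACC")
  m <- mask_homopolymers(aln)
  keep <- setdiff(seq_len(nchar(aln[[1]])), m$mask$column)
  rebuilt <- vapply(names(aln), function(id) {
    chars <- strsplit(aln[[id]], "")[[1]]
    paste(chars[keep], collapse = "")
  }, character(1))
  expect_identical(rebuilt, m$masked_alignment)
  # unmasked columns are untouched
  expect_identical(
    substr(m$masked_alignment[["a"]], 1, 2),
    substr(aln[["a"]], 1, 2)
  )
})

test_that("simple indel coding reproduces the published toy matrices", {
  one <- simple_indel_coding(c(t1 = "A--T", t2 = "ACGT", t3 = "ACGT"))
  expect_equal(ncol(one$matrix), 1)
  expect_equal(unname(one$matrix[, 1]), c("1", "0", "0"))
  # nested gaps: the containing gap scores ? for the smaller character
  two <- simple_indel_coding(c(t1 = "A---T", t2 = "A--GT"))
  expect_equal(ncol(two$matrix), 2)
  blocks <- two$blocks
  small <- which(blocks$col_start == 2 & blocks$col_end == 3)
  big <- which(blocks$col_start == 2 & blocks$col_end == 4)
  expect_equal(unname(two$matrix["t1", small]), "?")
  expect_equal(unname(two$matrix["t2", small]), "1")
  expect_equal(unname(two$matrix["t1", big]), "1")
  expect_equal(unname(two$matrix["t2", big]), "0")
  # gap-free alignment codes zero characters
  expect_equal(ncol(simple_indel_coding(c(a = "ACGT", b = "ACGT"))$matrix), 0)
})

test_that("simple indel coding agrees with the column-pattern oracle", {
  set.seed(21)
  for (rep in 1:8) {
    rows <- vapply(1:5, function(i) {
      chars <- sample(c("A", "C", "G", "T"), 60, TRUE)
      # plant 0-3 gap runs
      for (k in seq_len(sample(0:3, 1))) {
        s <- sample(50, 1)
        l <- sample(1:6, 1)
        chars[s:(s + l)] <- "-"
      }
      paste(chars, collapse = "")
    }, character(1))
    names(rows) <- paste0("t", 1:5)
    got <- simple_indel_coding(rows)
    want <- sic_oracle(rows)
    expect_identical(unname(got$matrix), unname(want))
  }
})

test_that("CDS concatenation produces a partitioned supermatrix", {
  genomes <- c(
    g1 = paste0("ATGAAACCCGGGTAA", "TTTTT", "ATGCATTGA"),
    g2 = paste0("ATGAAACCCGGATAA", "TTTTT", "ATGCACTGA")
  )
  ann <- tibble::tibble(
    gene = c("geneA", "geneB"), type = "CDS", strand = "+",
    start = c(1L, 21L), end = c(15L, 29L), exon = 1L
  )
  sm <- concatenate_cds(genomes, list(g1 = ann, g2 = ann))
  expect_equal(nchar(sm$matrix[["g1"]]), 24)
  expect_equal(nrow(sm$partitions), 2)
  expect_equal(sm$partitions$start, c(1L, 16L))
  expect_equal(sm$partitions$end, c(15L, 24L))
})

test_that("a gene missing from one genome is filled with ?", {
  genomes <- c(g1 = "ATGAAATAAGGG", g2 = "ATGAAATAACCC")
  ann1 <- tibble::tibble(gene = c("x", "y"), type = "CDS", strand = "+",
                         start = c(1L, 10L), end = c(9L, 12L), exon = 1L)
  ann2 <- ann1[1, ]
  sm <- concatenate_cds(genomes, list(g1 = ann1, g2 = ann2))
  expect_identical(substr(sm$matrix[["g2"]], 10, 12), "???")
})

test_that("minus-strand and intron-split genes are spliced correctly", {
  cds <- "ATGAAACCCTAA"
  genome <- paste0("GGGG", revcomp(cds), "TTTT")
  ann <- tibble::tibble(gene = "g", type = "CDS", strand = "-",
                        start = 5L, end = 16L, exon = 1L)
  sm <- concatenate_cds(c(a = genome), list(a = ann))
  expect_identical(sm$matrix[["a"]], cds)
})

test_that("phylogenetic writers emit parseable files", {
  sm <- concatenate_cds(
    c(g1 = "ATGAAATAA", g2 = "ATGAAGTAA"),
    list(
      g1 = tibble::tibble(gene = "x", type = "CDS", strand = "+",
                          start = 1L, end = 9L, exon = 1L),
      g2 = tibble::tibble(gene = "x", type = "CDS", strand = "+",
                          start = 1L, end = 9L, exon = 1L)
    )
  )
  phy <- tempfile(fileext = ".phy")
  write_phylip(sm, phy)
  lines <- readLines(phy)
  expect_match(lines[1], "2 9")
  part <- tempfile(fileext = ".txt")
  write_partitions(sm, part)
  expect_match(readLines(part), "DNA, x = 1-9")
  nex <- tempfile(fileext = ".nex")
  sic <- simple_indel_coding(c(g1 = "AC-T", g2 = "ACGT"))
  write_nexus(c(g1 = "AC-T", g2 = "ACGT"), sic, nex)
  nx <- readLines(nex)
  expect_true(any(grepl("#NEXUS", nx)))
  expect_true(any(grepl("RESTRICTION", nx)))
  expect_true(any(grepl("AC-T1", nx)))  # DNA row plus binary character
})
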