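test_that("segregating sites are classified by codon context", {
  aln <- c(g1 = "ATGTCACGT", g2 = "ATGTTACGT", g3 = "ATGTCACGT")
  s <- classify_segregating_sites(aln)
  expect_equal(nrow(s), 1)
  expect_equal(s$codon, 2)
  expect_equal(s$codon_pos, 2)
  expect_equal(s$class, "nonsynonymous")  # TCA (S) vs TTA (L)
  aln2 <- c(g1 = "ATGGTCAAA", g2 = "ATGGTTAAA")
  s2 <- classify_segregating_sites(aln2)
  expect_equal(s2$class, "synonymous")    # GTC vs GTT, both V
})

test_that("premature-stop alleles are flagged", {
  # CAA (Q) vs TAA (stop), as for the rpl20-like truncation
  aln <- c(g1 = "ATGCAAGGG", g2 = "ATGTAAGGG")
  s <- classify_segregating_sites(aln)
  expect_true(s$creates_stop)
  expect_equal(s$class, "nonsynonymous")
})

test_that("gapped codons are excluded with a logged tally", {
  aln <- c(g1 = "ATG-CAGGG", g2 = "ATGTCAGGG")
  s <- classify_segregating_sites(aln)
  expect_equal(attr(s, "excluded_codons"), 1)
  expect_equal(nrow(s), 0)
  expect_error(classify_segregating_sites(c(a = "ATGC", b = "ATGC")),
               "divisible")
})

test_that("classification agrees with a per-column brute-force translator", {
  set.seed(7)
  for (rep in 1:5) {
    n_codon <- 30
    base <- paste(sample(plastkit:::NONSTOP_CODONS, n_codon, TRUE),
                  collapse = "")
    rows <- vapply(1:4, function(i) {
      x <- base
      for (k in sample(nchar(base), 5)) {
        substr(x, k, k) <- sample(c("A", "C", "G", "T"), 1)
      }
      x
    }, character(1))
    names(rows) <- paste0("g", 1:4)
    got <- classify_segregating_sites(rows)
    # oracle: per column, compare translated codons over all genome pairs
    m <- do.call(rbind, strsplit(rows, ""))
    for (i in seq_len(nrow(got))) {
      col <- got$column[i]
      ci <- (col - 1) %/% 3 + 1
      cols <- (ci - 1) * 3 + 1:3
      codons <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      p <- (col - 1) %% 3 + 1
      alleles <- unique(m[, col])
      nonsyn <- FALSE
      for (g in seq_along(codons)) {
        for (alt in setdiff(alleles, m[g, col])) {
          mut <- codons[g]
          substr(mut, p, p) <- alt
          if (!identical(unname(Biostrings::GENETIC_CODE[codons[g]]),
                         unname(Biostrings::GENETIC_CODE[mut]))) {
            nonsyn <- TRUE
          }
        }
      }
      expect_identical(got$class[i],
                       if (nonsyn) "nonsynonymous" else "synonymous")
    }
    # every column with >= 2 alleles is reported
    seg_cols <- which(apply(m, 2, function(x) length(unique(x)) > 1))
    expect_setequal(got$column, seg_cols)
  }
})

test_that("gene summaries partition into the three classes", {
  sites <- tibble::tibble(
    gene = c("a", "a", "b"),
    class = c("synonymous", "nonsynonymous", "synonymous")
  )
  s <- summarize_genes(sites, c("a", "b", "c"))
  expect_equal(s$class, c("nonsynonymous", "synonymous-only", "identical"))
  expect_equal(sum(table(s$class)), 3)
})

test_that("NG86 site partition sums to 3 per codon", {
  for (cdn in sample(plastkit:::NONSTOP_CODONS, 12)) {
    st <- plastkit:::ng86_sites(cdn)
    expect_equal(unname(st["syn"] + st["nonsyn"]), 3)
  }
})

test_that("Ka/Ks handles degenerate pairs as specified", {
  same <- kaks_pairwise("ATGAAATTT", "ATGAAATTT")
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ka_ks))
  # TTT -> TTA: one nonsynonymous difference (F -> L), no synonymous
  one <- kaks_pairwise("TTT", "TTA")
  expect_equal(one$s_diffs, 0)
  expect_equal(one$n_diffs, 1)
  expect_gt(one$ka, 0)
  expect_equal(one$ks, 0)
  expect_true(is.na(one$ka_ks))
})

test_that("Ka/Ks is symmetric and matches exhaustive pathway enumeration", {
  set.seed(13)
  for (rep in 1:6) {
    n_codon <- sample(4:10, 1)
    s1 <- paste(sample(plastkit:::NONSTOP_CODONS, n_codon, TRUE),
                collapse = "")
    s2 <- s1
    # plant a few changes (occasionally multiple in one codon)
    for (k in sample(nchar(s1), sample(2:4, 1))) {
      substr(s2, k, k) <- sample(c("A", "C", "G", "T"), 1)
    }
    got <- kaks_pairwise(s1, s2)
    rev <- kaks_pairwise(s2, s1)
    expect_equal(got$ka, rev$ka, tolerance = 1e-12)
    expect_equal(got$ks, rev$ks, tolerance = 1e-12)
    want <- ng86_oracle(s1, s2)
    expect_equal(got$s_sites, want$S, tolerance = 1e-9)
    expect_equal(got$s_diffs, want$Sd, tolerance = 1e-9)
    expect_equal(got$n_diffs, want$Nd, tolerance = 1e-9)
    expect_equal(got$ks, want$ks, tolerance = 1e-9)
    expect_equal(got$ka, want$ka, tolerance = 1e-9)
  }
})

test_that("a planted 2-nonsynonymous + 1-synonymous toy matches the oracle", {
  s1 <- "ATGGTCTCAAAACCCGGGTTTGATCATGAA"  # 10 codons
  s2 <- s1
  substr(s2, 6, 6) <- "T"    # GTC -> GTT, synonymous
  substr(s2, 8, 8) <- "T"    # TCA -> TTA, S -> L
  substr(s2, 25, 25) <- "T"  # CAT -> TAT, H -> Y
  got <- kaks_pairwise(s1, s2)
  want <- ng86_oracle(s1, s2)
  expect_equal(got$s_diffs, 1)
  expect_equal(got$n_diffs, 2)
  expect_equal(got$ka / got$ks, want$ka / want$ks, tolerance = 1e-9)
})
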