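ref200 <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")

test_that("strand separation follows the dUTP convention", {
  pair <- toy_pair("p1", pos_fwd = 10, pos_rev = 60, ref = ref200)
  sep <- separate_strands(pair, "fr-firststrand")
  # read 1 reverse / read 2 forward => plus strand
  expect_equal(nrow(sep$plus), 2)
  expect_equal(nrow(sep$minus), 0)
  sep2 <- separate_strands(pair, "fr-secondstrand")
  expect_equal(nrow(sep2$minus), 2)
})

test_that("improper or inconsistent pairs are unassigned with a reason", {
  improper <- toy_read("q1", flag = 1 + 64, pos = 5, cigar = "10M",
                       seq = substr(ref200, 5, 14))[, -12]
  sep <- separate_strands(improper)
  expect_equal(sep$unassigned$reason, "not-properly-paired")
  # both mates claiming the same orientation is inconsistent
  bad <- dplyr::bind_rows(
    toy_read("q2", 1 + 2 + 64, 5, "10M", substr(ref200, 5, 14)),
    toy_read("q2", 1 + 2 + 128, 30, "10M", substr(ref200, 30, 39))
  )[, -12]
  sep2 <- separate_strands(bad)
  expect_equal(unique(sep2$unassigned$reason), "inconsistent-mate-flags")
  # partition is exhaustive
  expect_equal(nrow(sep2$plus) + nrow(sep2$minus) + nrow(sep2$unassigned),
               nrow(bad))
})

test_that("MTPT filter keeps candidate edits and discards real mismatches", {
  inserts <- tibble::tibble(plastid_start = 1L, plastid_end = 100L)
  # read with one C->T mismatch inside the interval: retained
  s <- substr(ref200, 1, 10)   # ACGTACGTAC
  edited <- s
  substr(edited, 2, 2) <- "T"  # C -> T
  r1 <- toy_read("a", 0, 1, "10M", edited, strand = "+")
  # read with an A->G mismatch: discarded
  gsub <- s
  substr(gsub, 1, 1) <- "G"
  r2 <- toy_read("b", 0, 1, "10M", gsub, strand = "+")
  # read outside the interval with mismatches: untouched
  far <- substr(ref200, 150, 159)
  substr(far, 3, 3) <- "A"
  r3 <- toy_read("c", 0, 150, "10M", far, strand = "+")
  reads <- dplyr::bind_rows(r1, r2, r3)
  out <- filter_mtpt_reads(reads, inserts, ref200)
  expect_setequal(out$retained$qname, c("a", "c"))
  expect_equal(out$discarded$qname, "b")
  # on the minus strand the candidate change is G->A
  gs <- substr(ref200, 1, 10)
  substr(gs, 3, 3) <- "A"  # G -> A
  r4 <- toy_read("d", 0, 1, "10M", gs, strand = "-")
  out2 <- filter_mtpt_reads(r4, inserts, ref200)
  expect_equal(out2$retained$qname, "d")
  out3 <- filter_mtpt_reads(dplyr::mutate(r4, strand = "+"), inserts, ref200)
  expect_equal(nrow(out3$retained), 0)
  expect_error(filter_mtpt_reads(reads, tibble::tibble(a = 1), ref200),
               "malformed")
})

test_that("low-quality mismatches do not trigger the MTPT filter", {
  inserts <- tibble::tibble(plastid_start = 1L, plastid_end = 100L)
  s <- substr(ref200, 1, 10)
  substr(s, 5, 5) <- "C"  # real mismatch (A -> C at pos 5)
  q <- strrep("I", 10)
  substr(q, 5, 5) <- "+"  # Q10, below the floor
  r <- toy_read("lq", 0, 1, "10M", s, qual = q, strand = "+")
  out <- filter_mtpt_reads(r, inserts, ref200)
  expect_equal(out$retained$qname, "lq")
})

test_that("depth of coverage counts aligned bases CIGAR-aware", {
  r <- toy_read("x", 0, 1, "100M", strrep("A", 100), strand = "+")
  cov <- depth_of_coverage(r, 100)
  expect_equal(sum(cov$depth[cov$strand == "+"]), 100)
  expect_equal(sum(cov$depth[cov$strand == "-"]), 0)
  feats <- tibble::tibble(gene = "g", type = "CDS", strand = "+",
                          start = 1L, end = 100L, exon = 1L)
  fc <- feature_coverage(cov, feats)
  expect_equal(fc$sense, 1.0)
  # D and N consume reference without adding depth
  rd <- toy_read("y", 0, 1, "4M2D4M", strrep("A", 8), strand = "+")
  covd <- depth_of_coverage(rd, 20)
  plus <- covd$depth[covd$strand == "+"]
  expect_equal(plus[1:10], c(1, 1, 1, 1, 0, 0, 1, 1, 1, 1))
  # empty read set gives all zeros
  cov0 <- depth_of_coverage(r[0, ], 50)
  expect_true(all(cov0$depth == 0))
  # reads past the reference end are an error (circular wrap unresolved)
  expect_error(depth_of_coverage(r, 50), "reference end")
})

test_that("TPM is mean depth rescaled to one million", {
  means <- tibble::tibble(feature = c("a", "b"), sense = c(1, 3))
  tpm <- compute_tpm(means)
  expect_equal(tpm$tpm, c(250000, 750000))
  one <- compute_tpm(tibble::tibble(feature = "a", sense = 2))
  expect_equal(one$tpm, 1e6)
  expect_error(compute_tpm(tibble::tibble(feature = "a", sense = 0)),
               "undefined")
})

test_that("TPM sums to one million for every simulated individual", {
  st <- small_study(1)
  h <- st$haplotypes$HAP1
  for (ind in head(st$samples$individual[st$samples$haplotype == "HAP1"], 2)) {
    sep <- separate_strands(st$reads[[ind]]$reads)
    cov <- depth_of_coverage(plastkit:::bind_strand_sets(sep),
                             nchar(h$sequence))
    fc <- feature_coverage(cov, h$features)
    tpm <- compute_tpm(dplyr::filter(fc, type == "CDS"))
    expect_equal(sum(tpm$tpm), 1e6, tolerance = 1e-6)
  }
})

test_that("antisense detection reports nothing without opposite coverage", {
  r <- toy_read("x", 0, 1, "100M", strrep("A", 100), strand = "+")
  feats <- tibble::tibble(gene = "g", type = "CDS", strand = "+",
                          start = 1L, end = 100L, exon = 1L)
  cov <- depth_of_coverage(r, 300)
  calls <- detect_antisense(cov, feats, floor = 1)
  expect_equal(nrow(calls), 0)  # only sense coverage over the gene
})

test_that("group comparison finds planted changes and nothing under the null", {
  set.seed(31)
  base_tpm <- function(sex) {
    tidyr::expand_grid(
      individual = paste0(sex, 1:3), feature = paste0("f", 1:20)
    ) |>
      dplyr::mutate(sex = sex,
                    tpm = rlnorm(dplyr::n(), log(5e4), 0.1))
  }
  null_tbl <- dplyr::bind_rows(base_tpm("F"), base_tpm("H"))
  res0 <- compare_groups(null_tbl, by = "sex")
  expect_s3_class(res0, "plast_group_test")
  expect_equal(glance(res0)$n_significant, 0)
  # identical tables in both groups: nothing significant
  same <- dplyr::bind_rows(
    base_tpm("F"),
    base_tpm("F") |> dplyr::mutate(sex = "H",
                                   individual = sub("F", "H", individual))
  )
  expect_equal(glance(compare_groups(same, by = "sex"))$n_significant, 0)
  # a planted 8-fold change has the smallest adjusted p
  fc_tbl <- null_tbl |>
    dplyr::mutate(tpm = ifelse(feature == "f7" & sex == "H", tpm * 8, tpm))
  res1 <- compare_groups(fc_tbl, by = "sex")
  expect_equal(res1$feature[which.min(res1$p_adj)], "f7")
  expect_error(
    compare_groups(dplyr::filter(fc_tbl, individual != "F2" | sex != "F"),
                   by = "sex"),
    NA
  )
  expect_error(
    compare_groups(dplyr::filter(null_tbl, !individual %in% c("F2", "F3")),
                   by = "sex"),
    "replicates"
  )
})
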