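ref60 <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")

test_that("pileup counts match a per-read brute-force scan on toy SAM", {
  # mixed CIGARs: match, deletion spanning a site, insertion, soft clip,
  # low-quality base, both strands
  reads <- dplyr::bind_rows(
    toy_read("r1", 0, 1, "10M", "ACGTACGTAC", strand = "+"),
    toy_read("r2", 0, 1, "10M", "ATGTACGTAC", strand = "+"),  # C2->T
    toy_read("r3", 0, 1, "4M3D6M", "ACGTTACGTA", strand = "+"),
    toy_read("r4", 16, 3, "3M2I5M", "GTAAACGTAC", "II++IIIIII",
             strand = "-"),
    toy_read("r5", 0, 7, "2S8M", "TTGTACGTAC", strand = "+"),
    toy_read("r6", 0, 2, "10M", "CGTACGTACG",
             qual = "+IIIIIIIII", strand = "+")  # low-qual ref match
  )
  got <- build_pileup(reads, ref60) |>
    dplyr::arrange(strand, pos) |>
    dplyr::select(strand, pos, depth, A, C, G, T) |>
    as.data.frame()
  want <- brute_pileup(reads, ref60) |>
    (\(d) d[order(d$strand, d$pos), c("strand", "pos", "depth",
                                      "A", "C", "G", "T")])()
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want, ignore_attr = TRUE)
  # spot checks from the construction
  p2 <- got[got$pos == 2 & got$strand == "+", ]
  expect_equal(p2$depth, 4)          # r1, r2, r3, r6
  expect_equal(p2$T, 1)              # the edited base of r2
  expect_equal(p2$C, 2)              # r1 and r3 (r6 low-qual excluded)
  # deleted positions get no contribution from r3
  p5 <- got[got$pos == 5 & got$strand == "+", ]
  expect_equal(p5$depth, 3)          # r1, r2, r6 but not r3 (D)
})

test_that("editing rates and reporting thresholds behave as specified", {
  mk <- function(C, T, depth, individual = "i1", pos = 2L, strand = "+") {
    tibble::tibble(pos = pos, strand = strand, ref = "C", depth = depth,
                   A = 0L, C = C, G = 0L, T = T, individual = individual)
  }
  # 93% edited at depth 500: reported
  res <- call_editing_sites(mk(35, 465, 500))
  expect_equal(nrow(dplyr::distinct(res$sites, pos)), 1)
  expect_equal(res$sites$rate, 0.93)
  # rate 2% but 10 edited bases: reported through the alternative trigger
  res2 <- call_editing_sites(mk(490, 10, 500))
  expect_equal(nrow(res2$sites), 1)
  # below depth floor: not reported
  res3 <- call_editing_sites(mk(10, 93, 103))
  expect_equal(nrow(res3$sites), 0)
  # raising min_depth never adds sites (monotonicity)
  p <- dplyr::bind_rows(mk(100, 150, 250), mk(350, 80, 430, pos = 9L))
  low <- call_editing_sites(p, editing_policy(min_depth = 200))
  high <- call_editing_sites(p, editing_policy(min_depth = 400))
  expect_true(all(
    dplyr::distinct(high$sites, pos)$pos %in%
      dplyr::distinct(low$sites, pos)$pos
  ))
})

test_that("candidate sites are only reference-C positions", {
  st <- small_study(1)
  ind <- st$samples$individual[1]
  h <- st$haplotypes$HAP1
  sep <- separate_strands(st$reads[[ind]]$reads)
  pu <- build_pileup(plastkit:::bind_strand_sets(sep), h$sequence)
  pu$individual <- ind
  called <- call_editing_sites(pu)
  ref_at <- function(p) substr(h$sequence, p, p)
  for (i in seq_len(nrow(dplyr::distinct(called$sites, pos, strand)))) {
    s <- dplyr::distinct(called$sites, pos, strand)[i, ]
    expect_identical(ref_at(s$pos), if (s$strand == "+") "C" else "G")
  }
})

test_that("codon effects are annotated in the field's notation", {
  # plus-strand gene: ATG TCA GTC CAA ACG TAA
  genome <- paste0("GGGG", "ATGTCAGTCCAAACGTAA", "GGGG")
  feats <- tibble::tibble(gene = "g", type = "CDS", strand = "+",
                          start = 5L, end = 22L, exon = 1L)
  sites <- tibble::tibble(
    pos = c(9L, 13L, 14L, 6L),  # TCA pos2, GTC pos3, CAA pos1, ATG pos2
    strand = "+"
  )
  ann <- annotate_editing_effects(sites, feats, genome)
  expect_equal(ann$effect[1], "TCA (S) => TTA (L)")
  expect_equal(ann$effect_class[1], "nonsynonymous")
  expect_equal(ann$effect_class[2], "silent")
  expect_equal(ann$codon_edited[2], "GTT")
  expect_equal(ann$effect_class[3], "stop-created")
  expect_match(ann$effect[3], "Stop")
  # ACG start codon: annotate the edited start
  genome2 <- paste0("GGGG", "ACGTCATAA", "GGGG")
  feats2 <- tibble::tibble(gene = "s", type = "CDS", strand = "+",
                           start = 5L, end = 13L, exon = 1L)
  ann2 <- annotate_editing_effects(tibble::tibble(pos = 6L, strand = "+"),
                                   feats2, genome2)
  expect_equal(ann2$effect_class, "start-created")
  expect_equal(ann2$effect, "ACG (T) => ATG (Start)")
})

test_that("intron and intergenic contexts are recognized", {
  genome <- paste0("GG", "ATGAAA", "CCCCC", "TTTTAA", "GGGGG")
  feats <- tibble::tibble(
    gene = "g", type = "CDS", strand = "+",
    start = c(3L, 14L), end = c(8L, 19L), exon = c(1L, 2L)
  )
  ann <- annotate_editing_effects(
    tibble::tibble(pos = c(10L, 22L), strand = "+"), feats, genome
  )
  expect_equal(ann$context, c("intron", "intergenic"))
})

test_that("conservation states follow the genomic base and edit lists", {
  ortho <- c(
    ref = "ATGTCAGTC",
    tx1 = "ATGTTAGTC",  # genomic T at the site
    tx2 = "ATGTCAGTC",  # C, known edited
    tx3 = "ATGTCAGTC",  # C, known unedited
    tx4 = "ATGTCAGTC",  # C, no information
    tx5 = "ATG--AGTC"   # gapped: unalignable
  )
  site <- tibble::tibble(context = "cds", t_pos = 5L)
  states <- classify_conservation(
    site, ortho, reference_taxon = "ref",
    edit_lists = list(tx2 = c(5L), tx3 = integer())
  )
  expect_equal(states$state[states$taxon == "tx1"], "T")
  expect_equal(states$state[states$taxon == "tx2"], "Edit")
  expect_equal(states$state[states$taxon == "tx3"], "C")
  expect_equal(states$state[states$taxon == "tx4"], "C?")
  expect_true(is.na(states$state[states$taxon == "tx5"]))
  # intergenic sites cannot be aligned across taxa
  igs <- classify_conservation(tibble::tibble(context = "intergenic"),
                               ortho, "ref")
  expect_true(all(is.na(igs$state)))
})

test_that("conservation recovers the planted ortholog panel states", {
  st <- small_study(1)
  h <- st$haplotypes$HAP1
  panel <- simulate_ortholog_panel(h)
  sites <- h$truth$edit_sites |>
    dplyr::filter(context == "cds") |>
    dplyr::mutate(t_pos = (codon - 1L) * 3L + codon_pos)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    g <- s$gene
    lists_g <- lapply(panel$edit_lists[panel$listed_taxa],
                      function(l) l[[g]] %||% integer())
    got <- classify_conservation(
      dplyr::mutate(s, context = "cds"), panel$alignments[[g]],
      reference_taxon = h$id, edit_lists = lists_g
    )
    want <- panel$truth |>
      dplyr::filter(gene == g, t_pos == s$t_pos)
    j <- dplyr::inner_join(got, want, by = "taxon")
    expect_equal(j$state.x, j$state.y)
  }
})

test_that("editing comparison detects a planted haplotype difference", {
  mk_group <- function(group, inds, rate, depth = 1000) {
    purrr::map(inds, function(i) {
      t <- rbinom(1, depth, rate)
      tibble::tibble(pos = 50L, strand = "+", individual = i,
                     depth = depth, c_count = depth - t, t_count = t,
                     rate = t / depth, haplotype = group)
    }) |> purrr::list_rbind()
  }
  set.seed(17)
  # 0% vs 6% at depth ~6000 pooled per group: detected
  s <- dplyr::bind_rows(
    mk_group("KRA", paste0("k", 1:6), 0.0),
    mk_group("KOV", paste0("v", 1:6), 0.06)
  )
  res <- compare_editing(s, by = "haplotype")
  expect_true(res$significant)
  # groups sort alphabetically: group1 = KOV (edited), group2 = KRA (not)
  expect_gt(res$rate1, res$rate2 + 0.001)
  # identical pooled counts: not significant
  s2 <- dplyr::bind_rows(
    mk_group("KRA", paste0("k", 1:6), 0.5),
    mk_group("KOV", paste0("v", 1:6), 0.5)
  )
  res2 <- compare_editing(s2, by = "haplotype")
  expect_false(res2$significant)
  expect_error(compare_editing(s[1:6, ], by = "haplotype"), "two groups")
})
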