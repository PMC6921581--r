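test_that("plastome structure is quadripartite by construction", {
  g <- small_study(1)$base
  b <- g$boundaries
  cfg <- g$config
  expect_equal(sum(b$length), cfg$plastome_length)
  expect_equal(b$length[b$region == "IRa"], cfg$ir_length)
  irb <- substr(g$sequence, b$start[b$region == "IRb"],
                b$end[b$region == "IRb"])
  ira <- substr(g$sequence, b$start[b$region == "IRa"],
                b$end[b$region == "IRa"])
  expect_identical(ira, revcomp(irb))
  # IR detection recovers the planted boundaries exactly
  found <- find_inverted_repeats(g$sequence, min_ir = 1000)
  expect_equal(
    as.data.frame(found[match(b$region, found$region), c("start", "end")]),
    as.data.frame(b[, c("start", "end")]),
    ignore_attr = TRUE
  )
})

test_that("the same seed reproduces byte-identical sequences and reads", {
  cfg <- small_sim_config(7)
  g1 <- simulate_plastome(cfg)
  g2 <- simulate_plastome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  h1 <- derive_haplotype(g1, "HAPX")
  h2 <- derive_haplotype(g2, "HAPX")
  expect_identical(h1$sequence, h2$sequence)
  r1 <- simulate_reads(h1, NULL, "HAPX_F1", config = cfg)
  r2 <- simulate_reads(h2, NULL, "HAPX_F1", config = cfg)
  expect_identical(r1$reads, r2$reads)
})

test_that("planted editing positions are reference C on their strand", {
  g <- small_study(1)$base
  for (i in seq_len(nrow(g$truth$edit_sites))) {
    s <- g$truth$edit_sites[i, ]
    b <- substr(g$sequence, s$pos, s$pos)
    expect_identical(b, if (s$strand == "+") "C" else "G")
  }
})

test_that("an unedited derivation is identical to its base", {
  g <- small_study(1)$base
  h <- derive_haplotype(g, "H0", n_substitutions = 0, n_indels = 0,
                        ssr_unit_changes = 0)
  expect_identical(h$sequence, g$sequence)
  aln <- planted_alignment(g, list(h))
  d <- plastome_distances(aln)
  expect_equal(d$substitutions, 0)
  expect_equal(d$indelblock, 0)
})

test_that("haplotype distances equal the planted counts exactly", {
  st <- small_study(1)
  aln <- st$alignment
  d <- plastome_distances(aln)
  cfg <- st$config
  for (h in c("HAP1", "HAP2")) {
    row <- d[d$genome1 == "REF" & d$genome2 == h, ]
    expect_equal(row$substitutions, cfg$n_substitutions)
    expect_equal(row$indelblock, cfg$n_indels)
    # "indel" counts gap positions, so it is at least the block count
    expect_gte(row$indel, row$indelblock)
  }
})

test_that("planted SSR sets are recovered exactly in base and haplotypes", {
  st <- small_study(1)
  for (g in c(list(st$base), st$haplotypes)) {
    found <- find_ssrs(g$sequence) |>
      dplyr::select(start, end, unit, unit_length, n_units)
    want <- g$truth$ssr |>
      dplyr::arrange(start) |>
      dplyr::select(start, end, unit, unit_length, n_units)
    expect_equal(as.data.frame(found), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("a substitution planted inside an IR appears in both copies", {
  # toy quadripartite layout: LSC 1-4, IRb 5-9, SSC 10-11, IRa 12-16
  b <- tibble::tibble(region = c("LSC", "IRb", "SSC", "IRa"),
                      start = c(1L, 5L, 10L, 12L),
                      end = c(4L, 9L, 11L, 16L))
  base <- paste0("AAAA", "GATTC", "CC", revcomp("GATTC"))
  mutated <- plastkit:::apply_sub_mirrored(base, 6L, "C", b)
  # the mirror position in IRa is complement-substituted too
  expect_identical(substr(mutated, 6, 6), "C")
  expect_identical(substr(mutated, 15, 15), "G")
  # counted per aligned column: the one event contributes two columns
  expect_equal(count_substitutions(base, mutated), 2)
  # IRa stays the exact reverse complement of IRb
  expect_identical(substr(mutated, 12, 16), revcomp(substr(mutated, 5, 9)))
})

test_that("mitochondrial inserts carry the planted divergence markers", {
  st <- small_study(1)
  m <- st$mito$HAP1
  cfg <- st$config
  expect_equal(nrow(m$inserts), nrow(cfg$mtpt_spec))
  for (i in seq_len(nrow(m$inserts))) {
    ins <- m$inserts[i, ]
    mk <- m$markers[m$markers$insert == ins$insert, ]
    expect_equal(nrow(mk), max(1, round(ins$divergence * ins$length)))
    # markers never mimic candidate edits
    expect_false(any(mk$ref == "C" & mk$alt == "T"))
    expect_false(any(mk$ref == "G" & mk$alt == "A"))
    # the mito copy differs from the plastid interval at exactly the markers
    copy <- substr(m$sequence, ins$mito_start, ins$mito_end)
    plast <- substr(st$haplotypes$HAP1$sequence, ins$plastid_start,
                    ins$plastid_end)
    diff <- which(strsplit(copy, "")[[1]] != strsplit(plast, "")[[1]])
    expect_equal(diff, mk$plastid_pos - ins$plastid_start + 1L)
  }
})

test_that("a 377 nt insert interval copies 377 bases", {
  g <- small_study(1)$haplotypes$HAP1
  cfg <- sim_config(seed = 2, mtpt_spec = tibble::tibble(
    length = 377L, divergence = 0.03
  ))
  m <- simulate_mito(g, cfg)
  expect_equal(m$inserts$length, 377L)
  expect_equal(m$inserts$plastid_end - m$inserts$plastid_start + 1L, 377L)
})

test_that("an empty insert table yields a plain mitochondrial genome", {
  g <- small_study(1)$haplotypes$HAP1
  cfg <- sim_config(seed = 1, mtpt_spec = tibble::tibble(
    length = integer(), divergence = double()
  ))
  m <- simulate_mito(g, cfg)
  expect_equal(nrow(m$inserts), 0)
  # the downstream MTPT filter removes nothing
  r <- st_reads <- small_study(1)$reads[[1]]$reads[1:200, ]
  sep <- separate_strands(r)
  out <- filter_mtpt_reads(plastkit:::bind_strand_sets(sep), m$inserts,
                           g$sequence)
  expect_equal(nrow(out$discarded), 0)
})

test_that("infeasible configurations fail with a named constraint", {
  expect_error(sim_config(plastome_length = 5000, ir_length = 2400),
               "plastome_length")
  expect_error(sim_config(ir_length = 500), "ir_length")
  tiny <- small_sim_config(1)
  tiny$n_genes <- 60L
  expect_error(simulate_plastome(tiny), "do not fit")
})

test_that("read generation conserves every read through the pipeline", {
  st <- small_study(1)
  ind <- st$samples$individual[1]
  h <- st$haplotypes[[st$samples$haplotype[1]]]
  m <- st$mito[[st$samples$haplotype[1]]]
  reads <- st$reads[[ind]]$reads
  sep <- separate_strands(reads)
  flt <- filter_mtpt_reads(plastkit:::bind_strand_sets(sep), m$inserts,
                           h$sequence)
  expect_equal(
    nrow(flt$retained) + nrow(flt$discarded) + nrow(sep$unassigned),
    nrow(reads)
  )
  # mate flags are internally consistent: nothing lands in unassigned
  expect_equal(nrow(sep$unassigned), 0)
})

test_that("per-site observed edit fractions follow the binomial model", {
  st <- small_study(1)
  h <- st$haplotypes$HAP2
  ind <- st$samples$individual[st$samples$haplotype == "HAP2"][1]
  sep <- separate_strands(st$reads[[ind]]$reads)
  pu <- build_pileup(plastkit:::bind_strand_sets(sep), h$sequence)
  pu$individual <- ind
  rates <- editing_rates_at(pu, h$truth$edit_sites)
  j <- dplyr::inner_join(rates, h$truth$edit_sites, by = c("pos", "strand"))
  for (i in seq_len(nrow(j))) {
    p <- j$rate_hap2[i]
    n <- j$c_count[i] + j$t_count[i]
    if (n < 50) next
    sd3 <- 3 * sqrt(p * (1 - p) / n) + 3 * st$config$error_rate
    expect_lt(abs(j$rate[i] - p), sd3 + 1e-9)
  }
  # a zero-rate site shows (almost) no high-quality T
  zero <- j[j$rate_hap2 == 0, ]
  if (nrow(zero)) {
    expect_lt(max(zero$rate), 0.01)
  }
})

test_that("an absent antisense transcript leaves its strand empty", {
  st <- small_study(1)
  h1 <- st$haplotypes$HAP1
  tr <- h1$truth$antisense
  off <- tr[tr$level_hap1 == 0, ]
  expect_gt(nrow(off), 0)
  ind <- st$samples$individual[st$samples$haplotype == "HAP1"][1]
  sep <- separate_strands(st$reads[[ind]]$reads)
  cov <- depth_of_coverage(plastkit:::bind_strand_sets(sep),
                           nchar(h1$sequence))
  for (i in seq_len(nrow(off))) {
    v <- cov$depth[cov$strand == off$strand[i]][off$start[i]:off$end[i]]
    expect_lt(mean(v), 5)  # nothing but stray error-free overlap
  }
})
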