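# Simulation configuration. Defaults define the emulated study design:
# a quadripartite toy plastome, two haplotypes, three female (F) and three
# hermaphrodite (H) individuals per haplotype, stranded paired-end reads
# with planted C-to-U editing, antisense transcripts and mitochondrial
# plastid-like insert (MTPT) contamination.

#' Simulation configuration
#'
#' Returns the configuration list consumed by [simulate_study()] and the
#' lower-level generators. Defaults are the package's study conditions: a
#' 30 kb quadripartite plastome with 4 kb inverted repeats, two derived
#' haplotypes separated from the ancestral sequence by 50 substitutions and
#' 10 indel events each (3 of which are unit-count changes at planted SSR
#' loci), 3 F + 3 H individuals per haplotype, 100 nt paired-end reads at a
#' mean per-base depth of 500 with 0.2% uniform base-call errors, and 5%
#' of reads in insert-homologous regions originating from diverged
#' mitochondrial copies.
#'
#' @param seed Integer seed; the same seed gives byte-identical outputs.
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `plast_sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome architecture
    plastome_length = 30000L,
    ir_length = 4000L,
    ssc_length = 5000L,
    n_genes = 16L,
    n_trna = 3L,
    gene_codon_range = c(90L, 260L),   # codons incl. stop
    intron_genes = 0.15,
    intron_length_range = c(80L, 200L),
    min_gene_gap = 450L,
    utr_length = 200L,
    # haplotype divergence
    n_haplotypes = 2L,
    n_substitutions = 50L,
    n_indels = 10L,
    ssr_unit_changes = 3L,
    indel_length_range = c(1L, 12L),
    # SSR planting: unit length x number of loci of that class
    ssr_spec = tibble::tibble(
      unit_length = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L),
      n_units = c(8L, 10L, 7L, 12L, 4L, 5L, 6L, 4L, 5L, 3L)
    ),
    # MTPT inserts: plastid-homologous intervals in the mitochondrial genome
    mtpt_spec = tibble::tibble(
      length = c(1000L, 377L),
      divergence = c(0.02, 0.03)
    ),
    mito_length = 20000L,
    mito_read_frac = 0.05,
    # expression
    expr_sdlog = 0.5,
    expr_clamp = c(0.5, 3),
    individual_noise_sdlog = 0.15,
    # sequencing
    individuals_per_sex = 3L,
    read_length = 100L,
    fragment_mean = 250,
    fragment_sd = 30,
    depth = 500,
    error_rate = 0.002,
    error_highq_frac = 0.05,
    base_quality_char = "I",   # Q40
    error_quality_char = "+",  # Q10, below the Q20 floor
    error_highq_char = "?",    # Q30, above the floor
    strandedness = "fr-firststrand"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    abort(sprintf("unknown sim_config fields: %s", paste(bad, collapse = ", ")))
  }
  cfg[names(over)] <- over
  cfg$lsc_length <- cfg$plastome_length - 2L * cfg$ir_length - cfg$ssc_length
  if (cfg$lsc_length <= 0) {
    abort("configuration error: plastome_length must exceed 2*ir_length + ssc_length")
  }
  if (cfg$ir_length < 1000L) {
    abort("configuration error: ir_length must be at least 1000")
  }
  structure(cfg, class = c("plast_sim_config", "list"))
}

# Planted editing-site plan. Codons and rates mirror the kinds of sites seen
# in plastid editomes: serine->leucine and histidine->tyrosine restorations
# at high rates, a silent site near 50%, a low-rate stop-creating site, a
# low-rate start-codon-creating ACG site, and one haplotype-specific site
# (edited ~6% in haplotype 2 only, 0 in haplotype 1). Rates are identical
# across sexes and individuals within a haplotype (the null condition).
editing_plan <- function() {
  tibble::tribble(
    ~kind,        ~codon_ref, ~codon_pos, ~rate_hap1, ~rate_hap2,
    "cds",        "TCA",      2L,         0.96,       0.96,
    "cds",        "TCA",      2L,         0.90,       0.88,
    "cds",        "CAT",      1L,         0.70,       0.85,
    "cds",        "TCG",      2L,         0.52,       0.80,
    "cds",        "TCA",      2L,         0.00,       0.06,   # psbZ-like
    "cds_stop",   "CAA",      1L,         0.13,       0.08,
    "cds_start",  "ACG",      2L,         0.13,       0.16,
    "cds_silent", "GTC",      3L,         0.32,       0.56,
    "cds",        "CCA",      2L,         0.89,       0.80,
    "cds_silent", "ATC",      3L,         0.29,       0.07,
    "cds",        "TCA",      2L,         0.93,       0.97,
    "cds",        "CAT",      1L,         0.84,       0.78,
    "cds",        "TCT",      2L,         0.87,       0.81,
    "cds",        "CCA",      2L,         0.73,       0.79,
    "cds",        "TCA",      2L,         0.60,       0.56,
    "cds",        "ACG",      2L,         0.30,       0.45,
    "intron",     NA,         NA,         0.93,       0.93,
    "intron",     NA,         NA,         0.69,       0.30,
    "igs",        NA,         NA,         0.92,       0.93,
    "igs",        NA,         NA,         0.50,       0.72,
    "igs",        NA,         NA,         0.83,       0.86,
    "igs",        NA,         NA,         0.23,       0.43
  )
}

# Antisense transcript plan: intervals are resolved against planted features
# at simulation time. One antisense RNA over a tRNA present in both
# haplotypes, one present in haplotype 2 only, and one over a CDS gene's
# 3' region in both haplotypes. Levels are relative to the mean gene level.
antisense_plan <- function() {
  tibble::tribble(
    ~target,   ~target_index, ~length, ~level_hap1, ~level_hap2,
    "tRNA",    1L,            450L,    1.3,         1.3,
    "tRNA",    2L,            400L,    0.0,         1.4,   # haplotype-2 only
    "CDS",     1L,            450L,    1.1,         1.1
  )
}
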