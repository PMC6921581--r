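# Stranded paired-end read simulation. Reads are emitted pre-aligned (true
# positions, all-M CIGARs) against the haplotype's own plastome. Editing is
# applied per fragment (both mates of a molecule share the edit state),
# sequencing errors per base, and a configurable fraction of reads
# originates from the diverged mitochondrial insert copies.

sam_flag <- function(first, reverse, mate_reverse) {
  1L + 2L +                      # paired, proper pair
    ifelse(reverse, 16L, 0L) +
    ifelse(mate_reverse, 32L, 0L) +
    ifelse(first, 64L, 128L)
}

#' Individual sample sheet for a simulated study
#'
#' @param config A [sim_config()].
#' @param haplotypes Character vector of haplotype ids.
#' @return Tibble `individual`, `haplotype`, `sex`, `replicate`.
#' @export
sim_individuals <- function(config, haplotypes = c("HAP1", "HAP2")) {
  k <- config$individuals_per_sex
  tidyr::expand_grid(
    haplotype = haplotypes,
    sex = c("F", "H"),
    replicate = seq_len(k)
  ) |>
    mutate(individual = sprintf("%s_%s%d", .data$haplotype, .data$sex,
                                .data$replicate)) |>
    select("individual", "haplotype", "sex", "replicate")
}

# transcript table for one haplotype: gene transcripts (gene span plus UTRs,
# sense strand, expression level) and antisense transcripts; tRNAs are lost
# during library preparation (level 0)
transcript_table <- function(genome, hap_col) {
  utr <- genome$config$utr_length
  genes <- genome$features |>
    group_by(.data$gene) |>
    summarise(type = first(.data$type), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    left_join(genome$truth$expression, by = "gene") |>
    mutate(
      level = if_else(.data$type == "tRNA", 0, .data$level),
      start = .data$start - utr, end = .data$end + utr,
      transcript = .data$gene
    )
  anti <- genome$truth$antisense |>
    transmute(
      transcript = .data$id, type = "antisense", strand = .data$strand,
      start = .data$start, end = .data$end,
      level = .data[[hap_col]]
    )
  bind_rows(
    genes |> select("transcript", "type", "strand", "start", "end", "level"),
    anti
  ) |>
    filter(.data$level > 0)
}

#' Simulate stranded paired-end reads for one individual
#'
#' Fragments are drawn uniformly within each transcript at a rate giving the
#' configured mean per-base depth scaled by the transcript's expression
#' level (with per-individual lognormal noise). Under the default
#' `fr-firststrand` (dUTP-style) convention, read 1 aligns antisense to the
#' transcript. C-to-U editing is applied per fragment with the site's true
#' rate (C->T in plus-strand transcripts, G->A in reference coordinates for
#' minus-strand transcripts). Uniform per-base sequencing errors get a base
#' quality below the Q20 floor except for a small high-quality fraction.
#' A configurable fraction of reads originates from mitochondrial insert
#' copies and carries the divergence markers.
#'
#' @param genome A `plast_genome` haplotype.
#' @param mito Result of [simulate_mito()] for the same haplotype (or NULL
#'   for no contamination).
#' @param individual Individual id (seed varies per individual).
#' @param rate_col Which truth rate column applies (`"rate_hap1"` or
#'   `"rate_hap2"`).
#' @param level_col Antisense level column (`"level_hap1"`/`"level_hap2"`).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `reads` (SAM-column tibble), `truth` (tibble `qname`,
#'   `origin`, `transcript`, `strand`) and `frag_edits` (ground-truth
#'   per-fragment edit assignments: `frag`, `qname`, `pos`, `alt`).
#' @export
simulate_reads <- function(genome, mito = NULL, individual = "HAP1_F1",
                           rate_col = "rate_hap1", level_col = "level_hap1",
                           config = genome$config, seed = config$seed) {
  ch <- utf8ToInt(individual)
  set.seed(child_seed(seed, 300L + sum(ch * seq_along(ch)) %% 600L))
  rl <- config$read_length
  n_ref <- nchar(genome$sequence)
  tx <- transcript_table(genome, level_col)
  tx$noise <- rlnorm(nrow(tx), 0, config$individual_noise_sdlog)

  frag_rows <- list()
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    len <- t$end - t$start + 1L
    if (len < rl) next
    n_pairs <- round(config$depth * t$level * t$noise * len / (2 * rl))
    if (n_pairs < 1) next
    fl <- pmin(len, pmax(rl, round(rnorm(n_pairs, config$fragment_mean,
                                         config$fragment_sd))))
    fs <- t$start + floor(runif(n_pairs) * (len - fl + 1))
    frag_rows[[i]] <- tibble(
      transcript = t$transcript, tx_strand = t$strand,
      frag_start = as.integer(fs), frag_len = as.integer(fl),
      origin = "plastid"
    )
  }
  # mitochondrial insert transcripts (plus strand), mapped back to the
  # homologous plastid interval
  if (!is.null(mito) && nrow(mito$inserts)) {
    for (i in seq_len(nrow(mito$inserts))) {
      ins <- mito$inserts[i, ]
      len <- ins$length
      if (len < rl) next
      n_pairs <- round(config$depth * config$mito_read_frac * len / (2 * rl))
      if (n_pairs < 1) next
      fl <- pmin(len, pmax(rl, round(rnorm(n_pairs, config$fragment_mean,
                                           config$fragment_sd))))
      fs <- ins$plastid_start + floor(runif(n_pairs) * (len - fl + 1))
      frag_rows[[length(frag_rows) + 1L]] <- tibble(
        transcript = sprintf("mtpt%d", ins$insert), tx_strand = "+",
        frag_start = as.integer(fs), frag_len = as.integer(fl),
        origin = "mito"
      )
    }
  }
  frags <- list_rbind(frag_rows)
  n_frag <- nrow(frags)
  frags$qname <- sprintf("%s_f%06d", individual, seq_len(n_frag))
  frags$frag_end <- frags$frag_start + frags$frag_len - 1L

  # per-fragment editing state at each covered site
  sites <- genome$truth$edit_sites
  site_edit <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    rate <- sites[[rate_col]][s]
    covering <- which(
      frags$origin == "plastid" &
        frags$tx_strand == sites$strand[s] &
        frags$frag_start <= sites$pos[s] &
        frags$frag_end >= sites$pos[s] &
        frags$transcript != "" # sense transcripts only by strand match
    )
    if (!length(covering) || rate <= 0) next
    edited <- covering[rbinom(length(covering), 1, rate) == 1]
    if (length(edited)) {
      site_edit[[s]] <- tibble(frag = edited, pos = sites$pos[s],
                               alt = if (sites$strand[s] == "+") "T" else "A")
    }
  }
  frag_edits <- list_rbind(site_edit)

  # divergence markers carried by mito fragments
  if (!is.null(mito) && nrow(mito$markers)) {
    mk <- mito$markers
    marker_rows <- list()
    mito_idx <- which(frags$origin == "mito")
    for (j in seq_len(nrow(mk))) {
      covering <- mito_idx[frags$frag_start[mito_idx] <= mk$plastid_pos[j] &
                             frags$frag_end[mito_idx] >= mk$plastid_pos[j]]
      if (length(covering)) {
        marker_rows[[j]] <- tibble(frag = covering, pos = mk$plastid_pos[j],
                                   alt = mk$alt[j])
      }
    }
    frag_edits <- bind_rows(frag_edits, list_rbind(marker_rows))
  }

  # two mates per fragment; read 1 is antisense to the transcript under
  # fr-firststrand, sense under fr-secondstrand
  first_is_antisense <- config$strandedness == "fr-firststrand"
  left_pos <- frags$frag_start
  right_pos <- frags$frag_end - rl + 1L
  plus_tx <- frags$tx_strand == "+"
  # the reverse-oriented mate is the right one; which mate is "read 1":
  # plus transcript: antisense mate = reverse = right mate
  r1_is_right <- if (first_is_antisense) plus_tx else !plus_tx

  mk_reads <- function(first) {
    is_right <- if (first) r1_is_right else !r1_is_right
    pos <- ifelse(is_right, right_pos, left_pos)
    rev <- is_right
    tibble(
      qname = frags$qname,
      flag = sam_flag(first, rev, !rev),
      rname = genome$id,
      pos = as.integer(pos),
      mapq = 60L,
      cigar = sprintf("%dM", rl),
      rnext = "=",
      pnext = as.integer(ifelse(is_right, left_pos, right_pos)),
      tlen = ifelse(is_right, -frags$frag_len, frags$frag_len),
      frag = seq_len(n_frag)
    )
  }
  reads <- bind_rows(mk_reads(TRUE), mk_reads(FALSE))

  # sequences: reference substring, then fragment edits, then errors
  # (work on plain vectors; per-element tibble assignment would copy the
  # whole column each time)
  seqv <- substring(genome$sequence, reads$pos, reads$pos + rl - 1L)
  qualv <- rep(strrep(config$base_quality_char, rl), nrow(reads))

  if (!is.null(frag_edits) && nrow(frag_edits)) {
    hit <- inner_join(
      reads |> mutate(row = row_number()) |>
        select("row", "frag", "pos"),
      frag_edits, by = "frag", relationship = "many-to-many",
      suffix = c("_read", "_site")
    ) |>
      mutate(offset = .data$pos_site - .data$pos_read + 1L) |>
      filter(.data$offset >= 1L, .data$offset <= rl)
    for (i in seq_len(nrow(hit))) {
      substr(seqv[hit$row[i]], hit$offset[i], hit$offset[i]) <- hit$alt[i]
    }
  }

  n_reads <- nrow(reads)
  n_err <- rbinom(n_reads, rl, config$error_rate)
  err_reads <- rep(seq_len(n_reads), n_err)
  if (length(err_reads)) {
    err_off <- as.integer(ceiling(runif(length(err_reads)) * rl))
    highq <- runif(length(err_reads)) < config$error_highq_frac
    qchar <- ifelse(highq, config$error_highq_char, config$error_quality_char)
    newb <- vapply(seq_along(err_reads), function(i) {
      old <- substr(seqv[err_reads[i]], err_off[i], err_off[i])
      sample(setdiff(DNA_BASES, old), 1)
    }, character(1))
    for (i in seq_along(err_reads)) {
      r <- err_reads[i]; o <- err_off[i]
      substr(seqv[r], o, o) <- newb[i]
      substr(qualv[r], o, o) <- qchar[i]
    }
  }
  reads$seq <- seqv
  reads$qual <- qualv

  truth <- frags |>
    transmute(qname = .data$qname, origin = .data$origin,
              transcript = .data$transcript, strand = .data$tx_strand)
  list(
    reads = reads |>
      select("qname", "flag", "rname", "pos", "mapq", "cigar",
             "rnext", "pnext", "tlen", "seq", "qual") |>
      arrange(.data$pos, .data$qname),
    truth = truth,
    frag_edits = if (is.null(frag_edits) || !nrow(frag_edits)) NULL else
      frag_edits |> mutate(qname = frags$qname[.data$frag])
  )
}

#' Simulate the full study: genomes, haplotypes, mitochondria and reads
#'
#' Convenience wrapper producing the ancestral plastome, the derived
#' haplotypes, one mitochondrial genome with plastid inserts per haplotype,
#' and stranded paired-end reads for every individual (3 F + 3 H per
#' haplotype by default).
#'
#' @param config A [sim_config()].
#' @return List of class `plast_study`: `base`, `haplotypes` (named list),
#'   `mito` (named list), `alignment` (planted multiple alignment),
#'   `samples` (sample sheet), `reads` (named list per individual of
#'   [simulate_reads()] results) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  base <- simulate_plastome(config)
  hap_ids <- paste0("HAP", seq_len(config$n_haplotypes))
  haps <- lapply(hap_ids, function(h) derive_haplotype(base, hap = h))
  names(haps) <- hap_ids
  mito <- lapply(haps, function(h) simulate_mito(h, config))
  aln <- planted_alignment(base, haps)
  samples <- sim_individuals(config, hap_ids)
  reads <- vector("list", nrow(samples))
  names(reads) <- samples$individual
  for (i in seq_len(nrow(samples))) {
    h <- samples$haplotype[i]
    hn <- match(h, hap_ids)
    reads[[i]] <- simulate_reads(
      haps[[h]], mito[[h]], individual = samples$individual[i],
      rate_col = paste0("rate_hap", hn),
      level_col = paste0("level_hap", hn),
      config = config, seed = config$seed
    )
  }
  structure(list(
    base = base, haplotypes = haps, mito = mito, alignment = aln,
    samples = samples, reads = reads, config = config
  ), class = "plast_study")
}
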