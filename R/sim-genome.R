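# Genome-level synthetic data: an annotated quadripartite toy plastome with
# planted SSRs and editing-site contexts, derived haplotypes with planted
# substitutions and indels, a mitochondrial genome carrying diverged plastid
# inserts, and the planted (true) alignments connecting them. Every planted
# feature is recorded as ground truth in final coordinates.

NONSTOP_CODONS <- {
  all3 <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0
  ))
  all3[!all3 %in% c("TAA", "TAG", "TGA")]
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

# substitute one base, mirroring into the complementary IR copy when inside
# an inverted repeat so IRa stays the exact reverse complement of IRb
apply_sub_mirrored <- function(sequence, pos, base, boundaries) {
  sequence <- str_assign(sequence, pos, base)
  irb <- boundaries[boundaries$region == "IRb", ]
  ira <- boundaries[boundaries$region == "IRa", ]
  if (nrow(irb) && pos >= irb$start && pos <= irb$end) {
    mirror <- ira$start + (irb$end - pos)
    sequence <- str_assign(sequence, mirror, comp_base(base))
  } else if (nrow(ira) && pos >= ira$start && pos <= ira$end) {
    mirror <- irb$start + (ira$end - pos)
    sequence <- str_assign(sequence, mirror, comp_base(base))
  }
  sequence
}

# the planted IR pair must be the MAXIMAL inverted repeat: the first base of
# the SSC must not extend the repeat by pairing with the last base of the SSC
# (the linear right-extension of the IRb/IRa pair)
enforce_ir_break <- function(sequence, boundaries) {
  irb <- boundaries[boundaries$region == "IRb", ]
  ira <- boundaries[boundaries$region == "IRa", ]
  p1 <- irb$end + 1L
  p2 <- ira$start - 1L
  if (substr(sequence, p1, p1) == comp_base(substr(sequence, p2, p2))) {
    avoid <- c(comp_base(substr(sequence, p2, p2)),
               substr(sequence, p1 - 1L, p1 - 1L),
               substr(sequence, p1 + 1L, p1 + 1L))
    sequence <- str_assign(sequence, p1, sample(setdiff(DNA_BASES, avoid), 1))
  }
  sequence
}

# remove unplanned SSRs by point substitutions outside protected intervals
scrub_ssrs <- function(sequence, protected = NULL, boundaries = NULL,
                       max_iter = 60L) {
  in_protected <- function(p) {
    !is.null(protected) && nrow(protected) &&
      any(p >= protected$start & p <= protected$end)
  }
  is_planted <- function(locus) {
    !is.null(protected) && nrow(protected) &&
      any(protected$start <= locus$start & protected$end >= locus$end &
            protected$planted)
  }
  for (iter in seq_len(max_iter)) {
    loci <- find_ssrs(sequence)
    todo <- loci[!vapply(seq_len(nrow(loci)), function(i) {
      is_planted(loci[i, ])
    }, logical(1)), , drop = FALSE]
    if (!nrow(todo)) return(sequence)
    fixed_any <- FALSE
    for (i in seq_len(nrow(todo))) {
      cand <- seq(todo$start[i], todo$end[i])
      cand <- cand[!vapply(cand, in_protected, logical(1))]
      if (!length(cand)) next
      p <- cand[ceiling(length(cand) / 2)]
      old <- substr(sequence, p, p)
      left <- if (p > 1) substr(sequence, p - 1, p - 1) else ""
      right <- if (p < nchar(sequence)) substr(sequence, p + 1, p + 1) else ""
      newb <- sample(setdiff(DNA_BASES, c(old, left, right)), 1)
      sequence <- if (is.null(boundaries)) {
        str_assign(sequence, p, newb)
      } else {
        apply_sub_mirrored(sequence, p, newb, boundaries)
      }
      fixed_any <- TRUE
    }
    if (!fixed_any) break
  }
  abort("configuration error: could not scrub unplanned SSRs (protected regions too dense)")
}

# generate an SSR-free CDS of n_codons codons (incl. final stop)
gen_cds_seq <- function(n_codons, start_codon = "ATG", max_tries = 50L) {
  for (tries in seq_len(max_tries)) {
    body <- sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE)
    s <- paste0(start_codon, paste(body, collapse = ""),
                sample(STOP_CODONS, 1))
    if (nrow(find_ssrs(s)) == 0) return(s)
  }
  abort("configuration error: could not generate SSR-free CDS")
}

gen_plain_seq <- function(len, max_tries = 50L) {
  for (tries in seq_len(max_tries)) {
    s <- random_dna(len)
    if (nrow(find_ssrs(s)) == 0) return(s)
  }
  abort("configuration error: could not generate SSR-free segment")
}

# non-periodic repeat unit of a given length
gen_ssr_unit <- function(u) {
  repeat {
    unit <- paste(sample(DNA_BASES, u, replace = TRUE), collapse = "")
    if (smallest_period(unit) == u) return(unit)
  }
}

# choose a position from `candidates` where forcing `base` does not create a
# repeat tract (checked in a local window)
place_forced_base <- function(sequence, candidates, base, max_tries = 50L) {
  for (tries in seq_len(max_tries)) {
    gpos <- sample(candidates, 1)
    trial <- str_assign(sequence, gpos, base)
    win <- substr(trial, max(1L, gpos - 8L),
                  min(nchar(trial), gpos + 8L))
    if (nrow(find_ssrs(win)) == 0) return(gpos)
  }
  abort("configuration error: cannot place forced editing base")
}

# map a transcript (spliced, 5'->3') position to a genomic position
transcript_to_genomic <- function(exons, t_pos) {
  exons <- exons[order(exons$exon), , drop = FALSE]
  lens <- exons$end - exons$start + 1L
  cum <- cumsum(lens)
  k <- which(t_pos <= cum)[1]
  within <- t_pos - (if (k > 1) cum[k - 1] else 0L)
  if (exons$strand[1] == "+") {
    exons$start[k] + within - 1L
  } else {
    exons$end[k] - within + 1L
  }
}

#' Simulate an annotated quadripartite plastome with ground truth
#'
#' Builds a toy circular plastome in the conventional LSC-IRb-SSC-IRa layout
#' (IRa the exact reverse complement of IRb), places non-overlapping CDS and
#' tRNA features in the single-copy regions (a fraction of CDS genes carry
#' one intron; one gene gets an ACG start codon whose editing creates the
#' start), plants SSR loci and the codon contexts for the editing plan, and
#' records everything as ground truth. The sequence is scrubbed so that the
#' planted SSR set is exactly the set [find_ssrs()] reports.
#'
#' @param config A [sim_config()] list.
#' @return A `plast_genome` list: `id`, `sequence`, `features`, `boundaries`,
#'   `truth` (list with `ssr`, `edit_sites`, `antisense`, `expression`) and
#'   `config`.
#' @export
simulate_plastome <- function(config = sim_config()) {
  set.seed(child_seed(config$seed, 1L))
  L <- config$lsc_length; IR <- config$ir_length; SC <- config$ssc_length
  n <- config$plastome_length

  boundaries <- tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(1L, L + 1L, L + IR + 1L, L + IR + SC + 1L),
    end = c(L, L + IR, L + IR + SC, n)
  ) |> mutate(length = .data$end - .data$start + 1L)

  irb_seq <- random_dna(IR)
  sequence <- paste0(random_dna(L), irb_seq, random_dna(SC), revcomp(irb_seq))
  sequence <- enforce_ir_break(sequence, boundaries)
  sequence <- scrub_ssrs(sequence, boundaries = boundaries)

  # --- place genes in LSC then SSC -----------------------------------------
  n_intron <- max(2L, round(config$intron_genes * config$n_genes))
  intron_idx <- seq_len(n_intron)  # first genes carry an intron
  regions <- list(
    c(boundaries$start[1] + 150L, boundaries$end[1] - 150L),
    c(boundaries$start[3] + 150L, boundaries$end[3] - 150L)
  )
  reg <- 1L
  cursor <- regions[[1]][1]
  feats <- list()
  gene_seqs <- list()
  place <- function(len) {
    gap <- config$min_gene_gap + sample(0:80, 1)
    if (cursor + gap + len - 1L > regions[[reg]][2]) {
      if (reg == 1L) {
        reg <<- 2L
        cursor <<- regions[[2]][1]
        if (cursor + gap + len - 1L > regions[[reg]][2]) {
          abort("configuration error: gene features do not fit in LSC+SSC")
        }
      } else {
        abort("configuration error: gene features do not fit in LSC+SSC")
      }
    }
    start <- cursor + gap
    cursor <<- start + len - 1L
    start
  }

  for (g in seq_len(config$n_genes)) {
    name <- sprintf("gene%02d", g)
    n_codons <- sample(seq(config$gene_codon_range[1],
                           config$gene_codon_range[2]), 1)
    cds <- gen_cds_seq(n_codons)
    strand <- sample(c("+", "-"), 1)
    has_intron <- g %in% intron_idx
    if (has_intron) {
      ilen <- sample(seq(config$intron_length_range[1],
                         config$intron_length_range[2]), 1)
      intron <- gen_plain_seq(ilen)
      brk <- 3L * sample(seq(10L, n_codons - 10L), 1)  # codon boundary
      tx <- paste0(substr(cds, 1, brk), intron,
                   substr(cds, brk + 1, nchar(cds)))
      len <- nchar(tx)
      start <- place(len)
      genomic <- if (strand == "+") tx else revcomp(tx)
      sequence <- str_assign(sequence, start, genomic)
      # exon ranks follow transcript order (5'->3')
      if (strand == "+") {
        ex_start <- c(start, start + brk + ilen)
        ex_end <- c(start + brk - 1L, start + len - 1L)
      } else {
        ex_start <- c(start + len - brk, start)
        ex_end <- c(start + len - 1L, start + nchar(cds) - brk - 1L)
      }
      ex <- tibble(
        gene = name, type = "CDS", strand = strand,
        start = ex_start, end = ex_end, exon = c(1L, 2L)
      )
    } else {
      len <- nchar(cds)
      start <- place(len)
      genomic <- if (strand == "+") cds else revcomp(cds)
      sequence <- str_assign(sequence, start, genomic)
      ex <- tibble(gene = name, type = "CDS", strand = strand,
                   start = start, end = start + len - 1L, exon = 1L)
    }
    feats[[name]] <- ex
    gene_seqs[[name]] <- cds
  }
  for (t in seq_len(config$n_trna)) {
    name <- sprintf("trn%02d", t)
    len <- sample(70:90, 1)
    s <- gen_plain_seq(len)
    strand <- sample(c("+", "-"), 1)
    start <- place(len)
    sequence <- str_assign(sequence, start,
                           if (strand == "+") s else revcomp(s))
    feats[[name]] <- tibble(gene = name, type = "tRNA", strand = strand,
                            start = start, end = start + len - 1L, exon = 1L)
  }
  features <- list_rbind(feats) |> arrange(.data$start)

  # --- plant editing-site contexts -----------------------------------------
  plan <- editing_plan()
  cds_plan <- plan[startsWith(plan$kind, "cds"), ]
  cds_genes <- unique(features$gene[features$type == "CDS"])
  # small configurations host fewer sites: trim the plan to the genes
  n_nonstart <- min(sum(cds_plan$kind != "cds_start"),
                    length(cds_genes) - 1L)
  cds_plan <- bind_rows(
    cds_plan[cds_plan$kind == "cds_start", ][1, ],
    head(cds_plan[cds_plan$kind != "cds_start", ], n_nonstart)
  )
  # expression levels (sampled now: intergenic editing sites are hosted in
  # the UTRs of well-expressed genes so their depth clears the floor)
  lv <- rlnorm(length(cds_genes), 0, config$expr_sdlog)
  lv <- pmin(pmax(lv, config$expr_clamp[1]), config$expr_clamp[2])
  expression <- tibble(gene = cds_genes, level = lv)
  gene_codons <- vapply(cds_genes, function(g) {
    nchar(gene_seqs[[g]]) %/% 3L
  }, integer(1))
  # host of the ACG start codon: the longest gene whose start replacement
  # does not create a repeat tract
  start_gene <- NULL
  for (gcand in cds_genes[order(-gene_codons)]) {
    if (nrow(find_ssrs(str_assign(gene_seqs[[gcand]], 1L, "ACG"))) == 0) {
      start_gene <- gcand
      break
    }
  }
  if (is.null(start_gene)) {
    abort("configuration error: no gene admits an ACG start codon")
  }
  hosts <- setdiff(sample(cds_genes), start_gene)
  edit_rows <- list()
  hi <- 0L
  for (i in seq_len(nrow(cds_plan))) {
    row <- cds_plan[i, ]
    if (row$kind == "cds_start") {
      gene <- start_gene
      new_codon <- "ACG"
    } else {
      hi <- hi + 1L
      gene <- hosts[hi]
      new_codon <- row$codon_ref
    }
    ex <- features[features$gene == gene, ]
    strand <- ex$strand[1]
    # overwrite the codon in the spliced CDS, then in the genome; re-pick the
    # codon if the overwrite would create a repeat tract inside the gene
    for (tries in 1:50) {
      codon_idx <- if (row$kind == "cds_start") 1L else
        sample(seq(5L, gene_codons[[gene]] - 5L), 1)
      trial <- str_assign(gene_seqs[[gene]],
                          (codon_idx - 1L) * 3L + 1L, new_codon)
      if (nrow(find_ssrs(trial)) == 0) break
      if (tries == 50) abort(sprintf("configuration error: cannot place edit codon (%s gene %s)", row$kind, gene))
    }
    for (p in 1:3) {
      t_pos <- (codon_idx - 1L) * 3L + p
      gpos <- transcript_to_genomic(ex, t_pos)
      b <- substr(new_codon, p, p)
      sequence <- str_assign(sequence, gpos,
                             if (strand == "+") b else comp_base(b))
    }
    gene_seqs[[gene]] <- str_assign(gene_seqs[[gene]],
                                    (codon_idx - 1L) * 3L + 1L, new_codon)
    site_t_pos <- (codon_idx - 1L) * 3L + row$codon_pos
    gpos <- transcript_to_genomic(ex, site_t_pos)
    edit_rows[[length(edit_rows) + 1L]] <- tibble(
      site = NA_integer_, context = "cds", kind = row$kind, gene = gene,
      strand = strand, pos = gpos, codon = codon_idx,
      codon_pos = row$codon_pos, ref_codon = new_codon,
      rate_hap1 = row$rate_hap1, rate_hap2 = row$rate_hap2
    )
  }
  # mark the edited-start gene
  features$type[features$gene == start_gene] <- "CDS"  # unchanged type; flag below

  intron_plan <- plan[plan$kind == "intron", ]
  intron_plan <- head(intron_plan, n_intron)
  intron_hosts <- cds_genes[intron_idx][seq_len(nrow(intron_plan))]
  for (i in seq_len(nrow(intron_plan))) {
    gene <- intron_hosts[i]
    ex <- features[features$gene == gene, ] |> arrange(.data$start)
    istart <- ex$end[1] + 1L
    iend <- ex$start[2] - 1L
    strand <- ex$strand[1]
    gpos <- place_forced_base(
      sequence, seq(istart + 10L, iend - 10L),
      if (strand == "+") "C" else "G"
    )
    sequence <- str_assign(sequence, gpos, if (strand == "+") "C" else "G")
    edit_rows[[length(edit_rows) + 1L]] <- tibble(
      site = NA_integer_, context = "intron", kind = "intron", gene = gene,
      strand = strand, pos = gpos, codon = NA_integer_,
      codon_pos = NA_integer_, ref_codon = NA_character_,
      rate_hap1 = intron_plan$rate_hap1[i], rate_hap2 = intron_plan$rate_hap2[i]
    )
  }

  igs_plan <- plan[plan$kind == "igs", ]
  well_expressed <- expression$gene[expression$level >= 1]
  if (length(well_expressed) < nrow(igs_plan)) {
    well_expressed <- expression$gene[order(-expression$level)]
  }
  igs_hosts <- head(well_expressed, nrow(igs_plan))
  igs_plan <- head(igs_plan, length(igs_hosts))
  for (i in seq_len(nrow(igs_plan))) {
    gene <- igs_hosts[i]
    ex <- features[features$gene == gene, ]
    strand <- ex$strand[1]
    gstart <- min(ex$start); gend <- max(ex$end)
    upstream <- (i %% 2L) == 0L
    cand <- if (upstream) gstart - (15:60) else gend + (15:60)
    gpos <- place_forced_base(sequence, cand,
                              if (strand == "+") "C" else "G")
    sequence <- str_assign(sequence, gpos, if (strand == "+") "C" else "G")
    edit_rows[[length(edit_rows) + 1L]] <- tibble(
      site = NA_integer_, context = "igs", kind = "igs", gene = gene,
      strand = strand, pos = gpos, codon = NA_integer_,
      codon_pos = NA_integer_, ref_codon = NA_character_,
      rate_hap1 = igs_plan$rate_hap1[i], rate_hap2 = igs_plan$rate_hap2[i]
    )
  }
  edit_sites <- list_rbind(edit_rows) |>
    arrange(.data$pos) |>
    mutate(site = row_number())

  # --- plant SSR loci in intergenic space ----------------------------------
  tx_iv <- features |>
    group_by(.data$gene) |>
    summarise(start = min(.data$start) - config$utr_length,
              end = max(.data$end) + config$utr_length, .groups = "drop")
  occupied <- bind_rows(
    tx_iv |> select("start", "end"),
    boundaries |> filter(.data$region %in% c("IRb", "IRa")) |>
      select("start", "end"),
    tibble(start = edit_sites$pos - 3L, end = edit_sites$pos + 3L)
  )
  junction <- c(boundaries$end[2] + 0:2, boundaries$start[4] - (1:3))
  free_pos <- setdiff(
    seq(10L, n - 10L),
    c(unlist(purrr::map2(occupied$start, occupied$end, seq)), junction)
  )
  ssr_rows <- list()
  spec <- config$ssr_spec
  for (i in seq_len(nrow(spec))) {
    u <- spec$unit_length[i]; k <- spec$n_units[i]
    tract_len <- u * k
    placed <- FALSE
    for (tries in 1:200) {
      p <- sample(free_pos, 1)
      span <- seq(p - 2L, p + tract_len + 1L)
      if (!all(span %in% free_pos)) next
      unit <- gen_ssr_unit(u)
      tract <- strrep(unit, k)
      sequence <- str_assign(sequence, p, tract)
      # flank bases must terminate the repeat on both sides
      lb <- sample(setdiff(DNA_BASES, c(substr(unit, u, u),
                                        substr(sequence, p - 2L, p - 2L),
                                        substr(unit, 1L, 1L))), 1)
      rb <- sample(setdiff(DNA_BASES, c(substr(unit, 1L, 1L),
                                        substr(sequence, p + tract_len + 1L,
                                               p + tract_len + 1L),
                                        substr(unit, u, u))), 1)
      sequence <- str_assign(sequence, p - 1L, lb)
      sequence <- str_assign(sequence, p + tract_len, rb)
      ssr_rows[[length(ssr_rows) + 1L]] <- tibble(
        locus = length(ssr_rows) + 1L, start = p, end = p + tract_len - 1L,
        unit = canonical_unit(unit), unit_length = u, n_units = k,
        length = tract_len
      )
      free_pos <- setdiff(free_pos, seq(p - 26L, p + tract_len + 25L))
      placed <- TRUE
      break
    }
    if (!placed) abort("configuration error: no intergenic space for SSR locus")
  }
  ssr <- list_rbind(ssr_rows)

  # final scrub: the detectable SSR set must equal the planted set exactly
  protected <- bind_rows(
    features |> transmute(start = .data$start, end = .data$end,
                          planted = FALSE),  # exons: no mutations in CDS
    ssr |> transmute(start = .data$start - 1L, end = .data$end + 1L,
                     planted = TRUE),
    tibble(start = edit_sites$pos - 1L, end = edit_sites$pos + 1L,
           planted = FALSE)
  )
  sequence <- scrub_ssrs(sequence, protected = protected,
                         boundaries = boundaries)
  for (pass in 1:5) {
    fixed <- enforce_ir_break(sequence, boundaries)
    if (identical(fixed, sequence)) break
    sequence <- scrub_ssrs(fixed, protected = protected,
                           boundaries = boundaries)
  }
  found <- find_ssrs(sequence) |> select("start", "end", "unit", "unit_length")
  planted_set <- ssr |> select("start", "end", "unit", "unit_length")
  if (nrow(found) != nrow(planted_set) ||
      nrow(anti_join(found, planted_set,
                     by = c("start", "end", "unit", "unit_length"))) > 0) {
    abort("configuration error: planted SSR set could not be isolated")
  }

  # --- antisense intervals --------------------------------------------------
  ap <- antisense_plan()
  as_rows <- list()
  trna <- features |> filter(.data$type == "tRNA") |> arrange(.data$start)
  cds1 <- features |> filter(.data$gene == hosts[1]) |> arrange(.data$start)
  for (i in seq_len(nrow(ap))) {
    row <- ap[i, ]
    tgt <- if (row$target == "tRNA") trna[row$target_index, ] else
      tibble(gene = hosts[1], strand = cds1$strand[1],
             start = max(cds1$end) - row$length + 1L, end = max(cds1$end))
    centre <- (tgt$start + tgt$end) %/% 2L
    half <- row$length %/% 2L
    as_rows[[i]] <- tibble(
      id = sprintf("as%02d", i),
      start = centre - half, end = centre - half + row$length - 1L,
      strand = if (tgt$strand == "+") "-" else "+",
      target = tgt$gene,
      level_hap1 = row$level_hap1, level_hap2 = row$level_hap2
    )
  }
  antisense <- list_rbind(as_rows)

  structure(list(
    id = "REF",
    sequence = sequence,
    features = features,
    boundaries = boundaries,
    truth = list(
      ssr = ssr,
      edit_sites = edit_sites,
      antisense = antisense,
      expression = expression,
      start_edited_gene = start_gene
    ),
    config = config
  ), class = "plast_genome")
}
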