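# Haplotype derivation from a simulated plastome: planted substitutions and
# indel events (some realized as SSR unit-count changes), exact coordinate
# lifting of all annotations and ground truth, and construction of the true
# (planted) pairwise and multiple alignments.

# lift a base-genome position through an edit table to haplotype coordinates
# (NA for positions inside a deletion)
lift_positions <- function(edits, pos) {
  dels <- edits[edits$type == "del", , drop = FALSE]
  ins <- edits[edits$type == "ins", , drop = FALSE]
  shift <- integer(length(pos))
  if (nrow(ins)) {
    o <- order(ins$pos)
    cl <- cumsum(ins$len[o])
    k <- findInterval(pos - 0.5, ins$pos[o])
    shift <- shift + ifelse(k > 0L, cl[pmax(k, 1L)], 0L)
  }
  in_del <- rep(FALSE, length(pos))
  if (nrow(dels)) {
    o <- order(dels$pos)
    dstart <- dels$pos[o]
    dend <- dels$pos[o] + dels$len[o] - 1L
    cl <- cumsum(dels$len[o])
    # deletions fully left of pos shift it left
    k <- findInterval(pos - 0.5, dend)
    shift <- shift - ifelse(k > 0L, cl[pmax(k, 1L)], 0L)
    # positions inside a deleted interval have no image
    j <- findInterval(pos, dstart)
    in_del <- j > 0L & pos <= dend[pmax(j, 1L)]
  }
  out <- as.integer(pos + shift)
  out[in_del] <- NA_integer_
  out
}

# apply an edit table (base coordinates) to a sequence
apply_edits <- function(sequence, edits) {
  if (!nrow(edits)) return(sequence)
  for (i in order(edits$pos, decreasing = TRUE)) {
    e <- edits[i, ]
    sequence <- switch(e$type,
      sub = str_assign(sequence, e$pos, e$alt),
      del = paste0(substr(sequence, 1L, e$pos - 1L),
                   substr(sequence, e$pos + e$len, nchar(sequence))),
      ins = paste0(substr(sequence, 1L, e$pos),
                   e$seq,
                   substr(sequence, e$pos + 1L, nchar(sequence)))
    )
  }
  sequence
}

#' Derive a haplotype from a simulated plastome
#'
#' Plants exactly `n_substitutions` substitutions and `n_indels` indel
#' events relative to the base genome, all outside the inverted repeats.
#' `ssr_unit_changes` of the indel events are realized as unit-count changes
#' at planted SSR loci (the natural mode of SSR polymorphism); the remaining
#' events are insertions or deletions of 1-12 bp in intergenic or intronic
#' sequence, separated by at least 25 bp so each event forms its own gap
#' block in the true alignment. All annotations and ground-truth records are
#' lifted to the haplotype's final coordinates.
#'
#' @param base A `plast_genome` from [simulate_plastome()].
#' @param hap Haplotype id (e.g. `"HAP1"`).
#' @param seed Integer seed.
#' @param n_substitutions,n_indels,ssr_unit_changes Override the counts in
#'   `base$config`.
#' @return A `plast_genome` whose `truth` additionally carries
#'   `divergence` (list with `edits`, `substitutions`, `indels`) and, in
#'   `ssr`, the lifted (possibly length-changed) SSR loci.
#' @export
derive_haplotype <- function(base, hap = "HAP1", seed = base$config$seed,
                             n_substitutions = base$config$n_substitutions,
                             n_indels = base$config$n_indels,
                             ssr_unit_changes = base$config$ssr_unit_changes) {
  cfg <- base$config
  set.seed(child_seed(seed, 100L + nchar(hap) + utf8ToInt(substr(hap, nchar(hap), nchar(hap)))))
  n <- nchar(base$sequence)
  b <- base$boundaries
  seq0 <- base$sequence

  exons <- base$features |> transmute(start = .data$start, end = .data$end)
  ir <- b |> filter(.data$region %in% c("IRa", "IRb")) |>
    select("start", "end")
  gene_ends <- base$features |>
    group_by(.data$gene) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  terminal_codons <- bind_rows(
    gene_ends |> transmute(start = .data$start, end = .data$start + 4L),
    gene_ends |> transmute(start = .data$end - 4L, end = .data$end)
  )
  # single-copy bases adjacent to the repeats: a substitution there could
  # extend the maximal inverted repeat past the planted boundary
  irb_end <- b$end[b$region == "IRb"]
  ira_start <- b$start[b$region == "IRa"]
  forbidden <- bind_rows(
    ir,
    tibble(start = c(irb_end + 1L, ira_start - 3L),
           end = c(irb_end + 3L, ira_start - 1L)),
    base$truth$ssr |> transmute(start = .data$start - 2L, end = .data$end + 2L),
    tibble(start = base$truth$edit_sites$pos - 2L,
           end = base$truth$edit_sites$pos + 2L),
    terminal_codons
  )
  forbidden_pos <- unique(unlist(purrr::map2(
    pmax(forbidden$start, 1L), pmin(forbidden$end, n), seq
  )))
  allowed <- setdiff(seq(5L, n - 5L), forbidden_pos)

  for (attempt in 1:40) {
  set.seed(child_seed(seed, 100L + attempt * 7L +
                        sum(utf8ToInt(hap)) %% 50L))
  # substitutions anywhere allowed (CDS included)
  sub_pos <- sort(sample(allowed, n_substitutions))
  sub_ref <- vapply(sub_pos, function(p) substr(seq0, p, p), character(1))
  sub_alt <- vapply(sub_ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                    character(1))
  subs <- tibble(type = "sub", pos = sub_pos, len = 1L,
                 ref = sub_ref, alt = sub_alt, seq = NA_character_,
                 ssr_locus = NA_integer_)

  # SSR unit-count changes (indel events at planted loci)
  thr <- ssr_thresholds()
  ssr <- base$truth$ssr
  # prefer di+/larger units (heteroplasmy-free markers), then fill with mono
  pref <- c(sample(which(ssr$unit_length >= 2L)),
            sample(which(ssr$unit_length == 1L)))
  change_loci <- pref[seq_len(ssr_unit_changes)]
  ssr_edit_rows <- list()
  for (li in change_loci) {
    u <- ssr$unit_length[li]; k <- ssr$n_units[li]
    min_units <- if (u == 1L) thr$mono_min_length else
      thr$min_units[[as.character(u)]]
    can_del <- k - 1L >= min_units
    delta <- if (can_del && runif(1) < 0.5) -sample(1:min(2L, k - min_units), 1)
             else sample(1:2, 1)
    unit_at_start <- substr(base$sequence, ssr$start[li], ssr$start[li] + u - 1L)
    if (delta > 0) {
      ssr_edit_rows[[length(ssr_edit_rows) + 1L]] <- tibble(
        type = "ins", pos = ssr$end[li], len = delta * u,
        ref = NA_character_, alt = NA_character_,
        seq = strrep(unit_at_start, delta), ssr_locus = li
      )
    } else {
      ssr_edit_rows[[length(ssr_edit_rows) + 1L]] <- tibble(
        type = "del", pos = ssr$end[li] + delta * u + 1L, len = -delta * u,
        ref = NA_character_, alt = NA_character_,
        seq = NA_character_, ssr_locus = li
      )
    }
  }

  # plain indels in intergenic/intronic space, well separated
  n_plain <- n_indels - ssr_unit_changes
  exon_pos <- unlist(purrr::map2(exons$start, exons$end, seq))
  indel_allowed <- setdiff(allowed, exon_pos)
  # keep clear of substitutions and SSR loci
  indel_allowed <- setdiff(
    indel_allowed,
    unique(c(outer(sub_pos, -3:3, `+`)))
  )
  plain_rows <- list()
  used <- bind_rows(ssr_edit_rows) |>
    (\(x) if (nrow(x)) x$pos else integer())()
  for (i in seq_len(n_plain)) {
    for (tries in 1:500) {
      p <- sample(indel_allowed, 1)
      len <- sample(seq(cfg$indel_length_range[1], cfg$indel_length_range[2]), 1)
      window <- seq(p - 25L, p + len + 25L)
      if (any(window %in% used) || !all(seq(p, p + len) %in% indel_allowed)) {
        if (tries == 500) abort("configuration error: no space for indels")
        next
      }
      is_ins <- runif(1) < 0.5
      plain_rows[[i]] <- if (is_ins) {
        tibble(type = "ins", pos = p, len = len, ref = NA_character_,
               alt = NA_character_, seq = gen_plain_seq(len),
               ssr_locus = NA_integer_)
      } else {
        tibble(type = "del", pos = p, len = len, ref = NA_character_,
               alt = NA_character_, seq = NA_character_,
               ssr_locus = NA_integer_)
      }
      used <- c(used, window)
      break
    }
  }
  edits <- bind_rows(subs, bind_rows(ssr_edit_rows), bind_rows(plain_rows)) |>
    arrange(.data$pos)

  hap_seq <- apply_edits(seq0, edits)

  # lift annotations and truth
  lift_tbl <- function(tb, cols = c("start", "end")) {
    for (cl in cols) tb[[cl]] <- lift_positions(edits, tb[[cl]])
    tb
  }
  features <- lift_tbl(base$features)
  boundaries <- lift_tbl(base$boundaries) |>
    mutate(length = .data$end - .data$start + 1L)
  edit_sites <- base$truth$edit_sites |>
    mutate(pos = lift_positions(edits, .data$pos))
  ssr_h <- ssr |>
    mutate(
      start = lift_positions(edits, .data$start),
      delta_units = 0L
    )
  for (j in seq_along(change_loci)) {
    li <- change_loci[j]
    e <- ssr_edit_rows[[j]]
    d <- if (e$type == "ins") e$len %/% ssr$unit_length[li] else
      -e$len %/% ssr$unit_length[li]
    ssr_h$delta_units[li] <- d
  }
  ssr_h <- ssr_h |>
    mutate(
      n_units = .data$n_units + .data$delta_units,
      length = .data$n_units * .data$unit_length,
      end = .data$start + .data$length - 1L
    )
  antisense <- lift_tbl(base$truth$antisense)

  # the haplotype's detectable SSR set must equal the lifted planted set;
  # resample the edit draw otherwise (edits can create chance repeats)
  found <- find_ssrs(hap_seq) |> select("start", "end", "unit", "unit_length")
  want <- ssr_h |> arrange(.data$start) |>
    select("start", "end", "unit", "unit_length")
  if (nrow(found) == nrow(want) &&
      nrow(anti_join(found, want,
                     by = c("start", "end", "unit", "unit_length"))) == 0) {
    break
  }
  if (attempt == 40) {
    abort("configuration error: haplotype edits kept colliding with SSR scan")
  }
  }

  structure(list(
    id = hap,
    sequence = hap_seq,
    features = features,
    boundaries = boundaries,
    truth = list(
      ssr = ssr_h,
      edit_sites = edit_sites,
      antisense = antisense,
      expression = base$truth$expression,
      start_edited_gene = base$truth$start_edited_gene,
      divergence = list(
        edits = edits,
        substitutions = filter(edits, .data$type == "sub"),
        indels = filter(edits, .data$type != "sub")
      )
    ),
    config = cfg
  ), class = "plast_genome")
}

#' Planted multiple alignment of a base genome and derived haplotypes
#'
#' Reconstructs the true alignment implied by the recorded edit operations:
#' every base-genome position is one column; each insertion contributes its
#' own column block (gapped in all other rows); deletions appear as gaps in
#' the deleted rows.
#'
#' @param base A `plast_genome` (the ancestral sequence).
#' @param haplotypes List of derived `plast_genome` objects (each carrying
#'   `truth$divergence$edits`).
#' @return Named character vector of gapped rows (base first).
#' @export
planted_alignment <- function(base, haplotypes) {
  n <- nchar(base$sequence)
  base_chars <- seq_chars(base$sequence)
  hap_ids <- vapply(haplotypes, function(h) h$id, character(1))

  ins_blocks <- list()
  for (h in haplotypes) {
    e <- h$truth$divergence$edits
    ins <- e[e$type == "ins", , drop = FALSE]
    if (nrow(ins)) {
      ins_blocks[[h$id]] <- ins |> select("pos", "len", "seq") |>
        mutate(hap = h$id)
    }
  }
  ins_all <- bind_rows(ins_blocks)
  if (nrow(ins_all)) ins_all <- arrange(ins_all, .data$pos, .data$hap)

  row_for <- function(chars_by_pos, ins_content) {
    # chars_by_pos: length-n vector; ins_content: function(block) -> string
    if (!nrow(ins_all)) return(paste(chars_by_pos, collapse = ""))
    pieces <- character(0)
    prev <- 0L
    for (bi in seq_len(nrow(ins_all))) {
      p <- ins_all$pos[bi]
      pieces <- c(pieces,
                  paste(chars_by_pos[(prev + 1L):p], collapse = ""),
                  ins_content(bi))
      prev <- p
    }
    if (prev < n) {
      pieces <- c(pieces, paste(chars_by_pos[(prev + 1L):n], collapse = ""))
    }
    paste(pieces, collapse = "")
  }

  out <- setNames(character(length(haplotypes) + 1L),
                  c(base$id, hap_ids))
  out[base$id] <- row_for(base_chars, function(bi) {
    strrep("-", ins_all$len[bi])
  })
  for (h in haplotypes) {
    e <- h$truth$divergence$edits
    chars <- base_chars
    subs <- e[e$type == "sub", , drop = FALSE]
    if (nrow(subs)) chars[subs$pos] <- subs$alt
    dels <- e[e$type == "del", , drop = FALSE]
    if (nrow(dels)) {
      for (i in seq_len(nrow(dels))) {
        chars[dels$pos[i]:(dels$pos[i] + dels$len[i] - 1L)] <- "-"
      }
    }
    out[h$id] <- row_for(chars, function(bi) {
      if (ins_all$hap[bi] == h$id) ins_all$seq[bi] else
        strrep("-", ins_all$len[bi])
    })
  }
  out
}

#' Simulate a mitochondrial genome with diverged plastid inserts
#'
#' Copies the configured plastid intervals into a random mitochondrial
#' backbone with the stated fraction of substituted positions recorded as
#' divergence markers. Marker substitutions never mimic candidate editing
#' changes (no C-to-T and no G-to-A replacements), so reads from the insert
#' copies are unambiguous ground truth for the MTPT read filter.
#'
#' @param genome A `plast_genome` (the haplotype whose mitochondrial genome
#'   is being emulated).
#' @param config A [sim_config()]; `mtpt_spec` gives insert lengths and
#'   divergence fractions.
#' @param seed Integer seed.
#' @return List: `sequence` (mito genome), `inserts` (tibble `insert`,
#'   `mito_start`, `mito_end`, `plastid_start`, `plastid_end`, `length`,
#'   `divergence`), `markers` (tibble `insert`, `plastid_pos`, `ref`,
#'   `alt`).
#' @export
simulate_mito <- function(genome, config = genome$config,
                          seed = config$seed) {
  set.seed(child_seed(seed, 200L))
  spec <- config$mtpt_spec
  if (!is.null(spec) && nrow(spec) &&
      any(spec$divergence < 0.005 | spec$divergence > 0.05)) {
    abort("mtpt divergence fraction must be in [0.005, 0.05]")
  }
  backbone <- random_dna(config$mito_length)
  if (is.null(spec) || !nrow(spec)) {
    return(list(
      sequence = backbone,
      inserts = tibble(insert = integer(), mito_start = integer(),
                       mito_end = integer(), plastid_start = integer(),
                       plastid_end = integer(), length = integer(),
                       divergence = double()),
      markers = tibble(insert = integer(), plastid_pos = integer(),
                       ref = character(), alt = character())
    ))
  }
  genes <- genome$features |>
    filter(.data$type == "CDS") |>
    group_by(.data$gene) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    arrange(.data$start)
  insert_rows <- list()
  marker_rows <- list()
  mito_cursor <- 2000L
  for (i in seq_len(nrow(spec))) {
    len <- spec$length[i]
    div <- spec$divergence[i]
    # first insert overlaps a gene (its transcripts masquerade as plastid
    # reads); later inserts start in downstream sequence
    g <- genes[min(i * 3L, nrow(genes)), ]
    pstart <- max(1L, g$start - 100L) + (i - 1L) * 30L
    pend <- pstart + len - 1L
    copy <- substr(genome$sequence, pstart, pend)
    n_mark <- max(1L, round(div * len))
    mpos <- sort(sample(seq_len(len), n_mark))
    ref <- vapply(mpos, function(p) substr(copy, p, p), character(1))
    alt <- vapply(ref, function(r) {
      choices <- setdiff(DNA_BASES, r)
      if (r == "C") choices <- setdiff(choices, "T")
      if (r == "G") choices <- setdiff(choices, "A")
      sample(choices, 1)
    }, character(1))
    for (j in seq_along(mpos)) copy <- str_assign(copy, mpos[j], alt[j])
    backbone <- str_assign(backbone, mito_cursor, copy)
    insert_rows[[i]] <- tibble(
      insert = i, mito_start = mito_cursor, mito_end = mito_cursor + len - 1L,
      plastid_start = pstart, plastid_end = pend, length = len,
      divergence = div
    )
    marker_rows[[i]] <- tibble(
      insert = i, plastid_pos = pstart + mpos - 1L, ref = ref, alt = alt
    )
    mito_cursor <- mito_cursor + len + 3000L
  }
  list(
    sequence = backbone,
    inserts = list_rbind(insert_rows),
    markers = list_rbind(marker_rows)
  )
}
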