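# C-to-U RNA editing: strand-resolved pileups, site calling with reporting
# thresholds, codon-effect annotation, cross-taxon conservation
# classification, and group comparison of editing rates.

#' Default editing reporting thresholds
#'
#' A site is reported when, in at least one individual, depth is at least
#' `min_depth` and either the editing rate reaches `min_rate` or the number
#' of edited (T) bases reaches `min_edited_bases` — the smaller of the two
#' criteria admits the site. Bases below `min_base_quality` are excluded
#' from allele counts (but remain in depth).
#'
#' @param min_rate Minimum editing rate (default 0.05).
#' @param min_edited_bases Alternative trigger (default 10).
#' @param min_depth Minimum mapped reads at the site (default 200).
#' @param min_base_quality Phred floor for counted bases (default 20).
#' @return Named list of thresholds.
#' @export
editing_policy <- function(min_rate = 0.05, min_edited_bases = 10,
                           min_depth = 200, min_base_quality = 20) {
  list(min_rate = min_rate, min_edited_bases = min_edited_bases,
       min_depth = min_depth, min_base_quality = min_base_quality)
}

#' Build a strand-resolved pileup
#'
#' CIGAR-aware per-position base counts for one strand-separated read set.
#' Bases below the quality floor are excluded from the A/C/G/T counts but
#' included in `depth`. Counts are of the reference-strand bases as written
#' in the SAM records.
#'
#' @param reads Read tibble with a `strand` column (post MTPT filtering).
#' @param reference Reference sequence string.
#' @param min_base_quality Phred floor (default 20).
#' @return A `plast_pileup` tibble: `pos`, `strand`, `ref`, `depth`, `A`,
#'   `C`, `G`, `T` for all covered positions.
#' @export
build_pileup <- function(reads, reference, min_base_quality = 20) {
  ref_length <- nchar(reference)
  cov <- depth_of_coverage(reads, ref_length)
  mm <- read_mismatches(reads, reference)
  mm$strand <- reads$strand[mm$row]
  ref_chars <- seq_chars(reference)

  # start from "every aligned base matches the reference at high quality",
  # then correct with the sparse mismatch and low-quality events
  out <- cov |>
    filter(.data$depth > 0) |>
    mutate(ref = ref_chars[.data$pos])
  for (b in DNA_BASES) out[[b]] <- ifelse(out$ref == b, out$depth, 0L)

  key <- function(pos, strand) paste0(strand, pos)
  out_key <- key(out$pos, out$strand)
  if (nrow(mm)) {
    # all mismatches leave the reference-base count
    dec <- mm |> count(.data$pos, .data$strand)
    i <- match(key(dec$pos, dec$strand), out_key)
    for (b in DNA_BASES) {
      sel <- out$ref[i] == b
      out[[b]][i[sel]] <- out[[b]][i[sel]] - dec$n[sel]
    }
    # high-quality mismatches enter the alternative-base count
    inc <- mm |>
      filter(.data$qual >= min_base_quality) |>
      count(.data$pos, .data$strand, .data$alt)
    j <- match(key(inc$pos, inc$strand), out_key)
    for (b in DNA_BASES) {
      sel <- inc$alt == b
      out[[b]][j[sel]] <- out[[b]][j[sel]] + inc$n[sel]
    }
  }
  # low-quality bases that MATCH the reference also leave the counts
  lowm <- lowqual_matching_bases(reads, reference, min_base_quality)
  if (nrow(lowm)) {
    dec2 <- lowm |> count(.data$pos, .data$strand)
    i2 <- match(key(dec2$pos, dec2$strand), out_key)
    for (b in DNA_BASES) {
      sel <- out$ref[i2] == b
      out[[b]][i2[sel]] <- out[[b]][i2[sel]] - dec2$n[sel]
    }
  }
  class(out) <- c("plast_pileup", class(out))
  out
}

# aligned bases below the quality floor that equal the reference base
# (low-quality mismatches are handled through the mismatch table)
lowqual_matching_bases <- function(reads, reference, min_base_quality) {
  low_class <- sprintf("[\\x21-\\x%x]", 33L + min_base_quality - 1L)
  has_low <- grepl(low_class, reads$qual, perl = TRUE)
  empty <- tibble(row = integer(), pos = integer(), strand = character())
  if (!any(has_low)) return(empty)
  lay <- cigar_layout(reads$cigar)
  out <- list()
  simple <- grepl("^[0-9]+M$", reads$cigar) & has_low
  if (any(simple)) {
    idx <- which(simple)
    m <- gregexpr(low_class, reads$qual[idx], perl = TRUE)
    n_off <- lengths(m)
    ridx <- rep(idx, n_off)
    off <- unlist(m)
    pos <- reads$pos[ridx] + off - 1L
    base <- substring(reads$seq[ridx], off, off)
    refb <- substring(reference, pos, pos)
    keep <- base == refb
    if (any(keep)) {
      out[[1L]] <- tibble(row = ridx[keep], pos = pos[keep],
                          strand = reads$strand[ridx[keep]])
    }
    has_low <- has_low & !simple
  }
  for (r in which(has_low)) {
    q <- utf8ToInt(reads$qual[r]) - 33L
    low_off <- which(q < min_base_quality)
    l <- lay[[reads$cigar[r]]]
    sc <- seq_chars(reads$seq[r])
    for (s in seq_len(nrow(l$m))) {
      seg <- l$m[s, ]
      in_seg <- low_off[low_off > seg$read_off &
                          low_off <= seg$read_off + seg$len]
      if (!length(in_seg)) next
      ref_at <- reads$pos[r] + seg$ref_off + (in_seg - seg$read_off) - 1L
      match_ref <- sc[in_seg] == vapply(ref_at, function(p) {
        substr(reference, p, p)
      }, character(1))
      if (any(match_ref)) {
        out[[length(out) + 1L]] <- tibble(
          row = r, pos = ref_at[match_ref], strand = reads$strand[r]
        )
      }
    }
  }
  if (!length(out)) return(empty)
  list_rbind(out)
}

#' Call C-to-U editing sites from per-individual pileups
#'
#' Candidate sites are positions whose reference base is C on the
#' transcribed strand: reference C in the plus-strand pileup (edits appear
#' as T) and reference G in the minus-strand pileup (edits appear as A in
#' reference coordinates; counts are complemented so the rate is always
#' T/(C+T) on the transcript). A site is reported when at least one
#' individual passes the policy thresholds. Sites that fail them in every
#' individual but show edited bases in all individuals are flagged
#' `below_threshold` (a consistently edited annex) rather than reported.
#'
#' @param pileups Tibble binding per-individual pileups, with an
#'   `individual` column.
#' @param policy An [editing_policy()].
#' @return A list with `sites` (tibble `pos`, `strand`, `individual`,
#'   `depth`, `c_count`, `t_count`, `rate`) for reported sites, and `annex`
#'   (same shape) for consistently edited below-threshold sites.
#' @export
call_editing_sites <- function(pileups, policy = editing_policy()) {
  cand <- pileups |>
    filter((.data$strand == "+" & .data$ref == "C") |
             (.data$strand == "-" & .data$ref == "G")) |>
    mutate(
      c_count = if_else(.data$strand == "+", .data$C, .data$G),
      t_count = if_else(.data$strand == "+", .data$T, .data$A),
      rate = if_else(.data$c_count + .data$t_count > 0,
                     .data$t_count / (.data$c_count + .data$t_count),
                     NA_real_)
    ) |>
    select("pos", "strand", "individual", "depth", "c_count", "t_count",
           "rate")
  n_ind <- n_distinct(cand$individual)
  status <- cand |>
    group_by(.data$pos, .data$strand) |>
    summarise(
      reported = any(.data$depth >= policy$min_depth &
                       (!is.na(.data$rate) & .data$rate >= policy$min_rate |
                          .data$t_count >= policy$min_edited_bases)),
      consistent = n() == n_ind && all(.data$t_count > 0),
      .groups = "drop"
    )
  keep <- status |> filter(.data$reported)
  annex <- status |> filter(!.data$reported, .data$consistent)
  list(
    sites = cand |>
      inner_join(keep |> select("pos", "strand"), by = c("pos", "strand")),
    annex = cand |>
      inner_join(annex |> select("pos", "strand"), by = c("pos", "strand"))
  )
}

#' Per-individual editing rates at given candidate positions
#'
#' Extracts C/T (complemented on the minus strand) counts and rates at the
#' supplied positions from a pileup, regardless of reporting thresholds —
#' used to look up the rate of a site in a sample group where it was not
#' itself called (e.g. a haplotype-specific site in the other haplotype).
#'
#' @param pileups Pileup tibble with an `individual` column.
#' @param positions Tibble with `pos` and `strand`.
#' @return Tibble `pos`, `strand`, `individual`, `depth`, `c_count`,
#'   `t_count`, `rate` (positions without coverage are absent).
#' @export
editing_rates_at <- function(pileups, positions) {
  pileups |>
    inner_join(positions |> distinct(.data$pos, .data$strand),
               by = c("pos", "strand")) |>
    mutate(
      c_count = if_else(.data$strand == "+", .data$C, .data$G),
      t_count = if_else(.data$strand == "+", .data$T, .data$A),
      rate = if_else(.data$c_count + .data$t_count > 0,
                     .data$t_count / (.data$c_count + .data$t_count),
                     NA_real_)
    ) |>
    select("pos", "strand", "individual", "depth", "c_count", "t_count",
           "rate")
}

#' Annotate the codon effect of an editing site
#'
#' For CDS sites, reports the codon before and after editing with the
#' encoded amino acids in the field's usual notation (e.g.
#' `"TCA (S) => TTA (L)"`), and flags silent edits, start-codon creation
#' (edited ACG at codon 1) and premature stop creation. Non-CDS sites are
#' classified by context (intron or intergenic).
#'
#' @param sites Tibble with `pos` and `strand` (one row per site).
#' @param features Feature tibble.
#' @param sequence Genome sequence.
#' @param utr Distance up/downstream of a gene still counted as its
#'   flanking intergenic context (annotation only).
#' @return `sites` with added `context`, `gene`, `codon`, `codon_pos`,
#'   `codon_ref`, `codon_edited`, `effect`, `effect_class`.
#' @export
annotate_editing_effects <- function(sites, features, sequence, utr = 100) {
  genes <- features |>
    group_by(.data$gene) |>
    summarise(type = first(.data$type), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  ann <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]; st <- sites$strand[i]
    row <- tibble(context = "intergenic", gene = NA_character_,
                  codon = NA_integer_, codon_pos = NA_integer_,
                  codon_ref = NA_character_, codon_edited = NA_character_,
                  effect = NA_character_, effect_class = NA_character_)
    host <- genes |>
      filter(.data$start <= p, .data$end >= p, .data$strand == st,
             .data$type == "CDS")
    if (nrow(host)) {
      g <- host$gene[1]
      ex <- features |> filter(.data$gene == g) |> arrange(.data$exon)
      # transcript coordinate of the site (NA if intronic)
      t_pos <- NA_integer_
      cum <- 0L
      for (e in seq_len(nrow(ex))) {
        w <- ex$end[e] - ex$start[e] + 1L
        if (p >= ex$start[e] && p <= ex$end[e]) {
          t_pos <- cum + if (st == "+") p - ex$start[e] + 1L else
            ex$end[e] - p + 1L
          break
        }
        cum <- cum + w
      }
      if (is.na(t_pos)) {
        row$context <- "intron"; row$gene <- g
      } else {
        codon_idx <- (t_pos - 1L) %/% 3L + 1L
        codon_pos <- (t_pos - 1L) %% 3L + 1L
        cstart <- (codon_idx - 1L) * 3L
        codon <- paste(vapply(1:3, function(k) {
          gp <- transcript_to_genomic(ex, cstart + k)
          b <- substr(sequence, gp, gp)
          if (st == "+") b else comp_base(b)
        }, character(1)), collapse = "")
        edited <- codon
        substr(edited, codon_pos, codon_pos) <- "T"
        aa0 <- translate_codon(codon); aa1 <- translate_codon(edited)
        eff_class <- if (codon_idx == 1L && codon == "ACG" &&
                           edited == "ATG") {
          "start-created"
        } else if (aa1 == "*" && aa0 != "*") {
          "stop-created"
        } else if (aa0 == aa1) "silent" else "nonsynonymous"
        label <- function(codon, aa) {
          sprintf("%s (%s)", codon,
                  if (aa == "*") "Stop" else aa)
        }
        eff <- sprintf("%s => %s", label(codon, aa0), label(edited, aa1))
        if (eff_class == "start-created") {
          eff <- sprintf("%s (T) => %s (Start)", codon, edited)
        }
        ref_codon_str <- codon
        row <- tibble(context = "cds", gene = g, codon = codon_idx,
                      codon_pos = codon_pos, codon_ref = ref_codon_str,
                      codon_edited = edited, effect = eff,
                      effect_class = eff_class)
      }
    } else {
      near <- genes |>
        filter(.data$start - utr <= p, .data$end + utr >= p)
      if (nrow(near)) row$gene <- near$gene[1]
      # could still be inside a tRNA/rRNA on either strand
      inside <- genes |>
        filter(.data$start <= p, .data$end >= p)
      if (nrow(inside) && all(inside$type != "CDS")) {
        row$context <- "intergenic"
      }
    }
    ann[[i]] <- row
  }
  bind_cols(sites, list_rbind(ann))
}

#' Classify cross-taxon conservation of an editing site
#'
#' Given an orthologous CDS alignment containing the reference taxon, the
#' homologous position of each taxon is classified: `"T"` if the taxon has
#' genomic T (editing hard-wired in DNA), `"Edit"` if it has C and the
#' taxon's known-edit list contains the position, `"C"` if it has C and is
#' known unedited, `"C?"` if it has C with no editing information, and `NA`
#' if the column is gapped/unalignable. Intergenic sites are `NA` for all
#' taxa (they cannot be reliably aligned across species).
#'
#' @param site One-row tibble with `context` and, for CDS sites,
#'   `gene`-level transcript position `t_pos` (position in the ungapped
#'   reference CDS).
#' @param ortho Named character vector: aligned CDS across taxa including
#'   `reference_taxon`. Bases on the transcribed (coding) strand.
#' @param reference_taxon Name of the reference row.
#' @param edit_lists Named list (per taxon) of integer vectors of known
#'   edited CDS positions; a taxon present here with the position absent is
#'   "known unedited" (`"C"`), a taxon absent entirely gives `"C?"`.
#' @return Tibble `taxon`, `state`.
#' @export
classify_conservation <- function(site, ortho, reference_taxon,
                                  edit_lists = list()) {
  taxa <- setdiff(names(ortho), reference_taxon)
  if (!identical(site$context, "cds")) {
    return(tibble(taxon = taxa, state = NA_character_))
  }
  map <- aln_column_map(ortho[[reference_taxon]])
  col <- map[site$t_pos]
  states <- vapply(taxa, function(tx) {
    b <- substr(ortho[[tx]], col, col)
    if (b == "-" || b == "N") return(NA_character_)
    if (b == "T") return("T")
    if (b == "C") {
      if (!tx %in% names(edit_lists)) return("C?")
      if (site$t_pos %in% edit_lists[[tx]]) return("Edit")
      return("C")
    }
    # a different base altogether: no editing information
    "C?"
  }, character(1))
  tibble(taxon = taxa, state = unname(states))
}

#' Compare editing rates between groups
#'
#' Per site, pools edited/unedited counts within each group and applies a
#' two-proportion test, with Benjamini-Hochberg adjustment across sites;
#' per-group mean and SD of the per-individual rates are also reported.
#' Sites with undefined rates in a whole group are skipped.
#'
#' @param sites Site-by-individual tibble from [call_editing_sites()]
#'   joined with sample metadata (so the grouping column is present).
#' @param by Grouping column (e.g. `"sex"` or `"haplotype"`).
#' @param alpha FDR level (default 0.05).
#' @return A `plast_editing_test` tibble: `pos`, `strand`, per-group pooled
#'   rates, means, SDs, `p_value`, `p_adj`, `significant`.
#' @export
compare_editing <- function(sites, by, alpha = 0.05) {
  groups <- sort(unique(sites[[by]]))
  if (length(groups) != 2) abort("exactly two groups are required")
  res <- sites |>
    filter(!is.na(.data$rate)) |>
    group_by(.data$pos, .data$strand) |>
    summarise(
      n1 = sum(.data[[by]] == groups[1]),
      n2 = sum(.data[[by]] == groups[2]),
      t1 = sum(.data$t_count[.data[[by]] == groups[1]]),
      c1 = sum(.data$c_count[.data[[by]] == groups[1]]),
      t2 = sum(.data$t_count[.data[[by]] == groups[2]]),
      c2 = sum(.data$c_count[.data[[by]] == groups[2]]),
      mean1 = mean(.data$rate[.data[[by]] == groups[1]]),
      mean2 = mean(.data$rate[.data[[by]] == groups[2]]),
      sd1 = sd(.data$rate[.data[[by]] == groups[1]]),
      sd2 = sd(.data$rate[.data[[by]] == groups[2]]),
      .groups = "drop"
    ) |>
    filter(.data$n1 >= 2, .data$n2 >= 2) |>
    mutate(
      rate1 = .data$t1 / (.data$t1 + .data$c1),
      rate2 = .data$t2 / (.data$t2 + .data$c2)
    )
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    m <- rbind(c(res$t1[i], res$c1[i]), c(res$t2[i], res$c2[i]))
    tryCatch(suppressWarnings(stats::prop.test(m)$p.value),
             error = function(e) 1)
  }, numeric(1))
  res <- res |>
    mutate(
      p_value = replace_na(.data$p_value, 1),
      p_adj = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_adj < alpha,
      group1 = groups[1], group2 = groups[2]
    )
  class(res) <- c("plast_editing_test", class(res))
  attr(res, "by") <- by
  attr(res, "alpha") <- alpha
  res
}
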