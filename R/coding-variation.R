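# Segregating-site classification in protein-coding alignments and pairwise
# Ka/Ks by the Nei-Gojobori (1986) method with Jukes-Cantor correction.

#' Classify segregating sites in a protein-coding alignment
#'
#' A column is segregating when at least two distinct unambiguous bases occur
#' across the aligned genomes. The site is classified nonsynonymous if any
#' observed allele changes the encoded amino acid relative to any other
#' allele in its codon context, holding the other two codon positions at
#' each genome's own state; otherwise synonymous. Alleles creating a
#' premature stop codon are flagged. Codons containing a gap or N in any
#' genome are excluded from consideration (their count is reported in the
#' `excluded_codons` attribute).
#'
#' @param alignment Named character vector of in-frame, equal-length aligned
#'   CDS rows (one per genome).
#' @param gene Gene name used in error messages.
#' @return Tibble with one row per segregating site: `column` (alignment
#'   column), `codon` (codon index), `codon_pos` (1-3), `alleles`
#'   (comma-separated), `class` (`"synonymous"`/`"nonsynonymous"`),
#'   `creates_stop`. Attribute `excluded_codons` carries the number of
#'   gap/N codons skipped.
#' @export
classify_segregating_sites <- function(alignment, gene = "gene") {
  stopifnot(length(alignment) >= 2)
  len <- unique(nchar(alignment))
  if (length(len) != 1) abort(sprintf("%s: rows differ in aligned length", gene))
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  ok_col <- apply(m, 2, function(col) all(col %in% DNA_BASES))
  codon_of_col <- (seq_len(len) - 1L) %/% 3L + 1L
  if (len %% 3L != 0L) {
    abort(sprintf("%s: alignment length %d not divisible by 3", gene, len))
  }
  codon_ok <- tapply(ok_col, codon_of_col, all)
  excluded <- sum(!codon_ok)
  out <- list()
  for (ci in which(codon_ok)) {
    cols <- (ci - 1L) * 3L + 1:3
    codons <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    for (p in 1:3) {
      alleles <- unique(m[, cols[p]])
      if (length(alleles) < 2) next
      nonsyn <- FALSE
      stopflag <- FALSE
      for (g in seq_along(codons)) {
        for (alt in setdiff(alleles, m[g, cols[p]])) {
          mut <- codons[g]
          substr(mut, p, p) <- alt
          aa0 <- translate_codon(codons[g])
          aa1 <- translate_codon(mut)
          if (!identical(aa0, aa1)) nonsyn <- TRUE
          if (identical(aa1, "*") && !identical(aa0, "*")) stopflag <- TRUE
        }
      }
      out[[length(out) + 1L]] <- tibble(
        column = cols[p], codon = ci, codon_pos = p,
        alleles = paste(sort(alleles), collapse = ","),
        class = if (nonsyn) "nonsynonymous" else "synonymous",
        creates_stop = stopflag
      )
    }
  }
  res <- if (length(out)) list_rbind(out) else tibble(
    column = integer(), codon = integer(), codon_pos = integer(),
    alleles = character(), class = character(), creates_stop = logical()
  )
  attr(res, "excluded_codons") <- excluded
  res
}

#' Summarize genes by their segregating-site content
#'
#' Partitions genes into `identical` (no segregating site),
#' `synonymous-only`, and `nonsynonymous` (at least one nonsynonymous
#' segregating site). Classes are exhaustive and disjoint.
#'
#' @param sites Tibble of segregating sites with a `gene` column (e.g.
#'   [classify_segregating_sites()] results bound over genes).
#' @param genes Character vector of all genes analysed (genes absent from
#'   `sites` are classed `identical`).
#' @return Tibble `gene`, `n_synonymous`, `n_nonsynonymous`, `class`.
#' @export
summarize_genes <- function(sites, genes) {
  per <- sites |>
    group_by(.data$gene) |>
    summarise(
      n_synonymous = sum(.data$class == "synonymous"),
      n_nonsynonymous = sum(.data$class == "nonsynonymous"),
      .groups = "drop"
    )
  tibble(gene = genes) |>
    left_join(per, by = "gene") |>
    mutate(
      across(c("n_synonymous", "n_nonsynonymous"), ~replace_na(.x, 0L)),
      class = dplyr::case_when(
        .data$n_nonsynonymous > 0 ~ "nonsynonymous",
        .data$n_synonymous > 0 ~ "synonymous-only",
        TRUE ~ "identical"
      )
    )
}

# NG86 per-codon site partition: fraction of the three possible changes at
# each position that are synonymous; changes to stop codons count as
# nonsynonymous so the syn + nonsyn fractions always sum to 3 per codon.
ng86_sites <- function(codon) {
  aa <- translate_codon(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (!is_stop_codon(mut) && identical(translate_codon(mut), aa)) {
        s <- s + 1 / 3
      }
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

# syn/nonsyn differences between two codons, averaged over all minimal
# mutational pathways; pathways passing through a stop codon are excluded
# (equal weight on the remainder; if all are blocked, all are used and the
# result is flagged via the "blocked" element).
ng86_differences <- function(c1, c2) {
  pos <- which(seq_chars(c1) != seq_chars(c2))
  if (!length(pos)) return(c(syn = 0, nonsyn = 0, blocked = 0))
  perms <- if (length(pos) == 1) {
    list(pos)
  } else {
    pp <- combinat_permutations(pos)
    pp
  }
  path_counts <- lapply(perms, function(order) {
    cur <- c1
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop_codon(nxt) && !is_stop_codon(c2)) ok <- FALSE
      if (identical(translate_codon(cur), translate_codon(nxt))) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd, ok = ok)
  })
  mat <- do.call(rbind, path_counts)
  use <- mat[, "ok"] == 1
  blocked <- if (!any(use)) 1 else 0
  if (!any(use)) use <- rep(TRUE, nrow(mat))
  c(
    syn = mean(mat[use, "sd"]),
    nonsyn = mean(mat[use, "nd"]),
    blocked = blocked
  )
}

combinat_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites per codon (each position's
#' fraction over the three possible changes, changes to stop codons counted
#' as nonsynonymous), averages differences over all minimal mutational
#' pathways between differing codons with equal weight (pathways through
#' stop codons excluded), and applies the Jukes-Cantor correction to the
#' proportions pN and pS. Codons containing a gap or N in either sequence
#' are excluded. When pN or pS reaches 3/4 the correction is undefined and
#' the corresponding estimate is `NA` with `saturated = TRUE`.
#'
#' @param seq1,seq2 In-frame aligned CDS strings of equal length.
#' @param gene Gene label carried into the result.
#' @return One-row tibble: `gene`, `s_sites`, `n_sites`, `s_diffs`,
#'   `n_diffs`, `ps`, `pn`, `ks`, `ka`, `ka_ks` (NA when Ks is 0 or
#'   undefined), `excluded_codons`, `blocked_paths`, `saturated`.
#' @examples
#' kaks_pairwise("TTTAAAGGG", "TTAAAAGGG")
#' @export
kaks_pairwise <- function(seq1, seq2, gene = NA_character_) {
  if (nchar(seq1) != nchar(seq2)) abort("sequences must be aligned (equal length)")
  if (nchar(seq1) %% 3 != 0) abort("aligned length must be divisible by 3")
  n_codons <- nchar(seq1) %/% 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; excluded <- 0L; blocked <- 0L
  for (ci in seq_len(n_codons)) {
    c1 <- substr(seq1, 3 * ci - 2, 3 * ci)
    c2 <- substr(seq2, 3 * ci - 2, 3 * ci)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) {
      excluded <- excluded + 1L
      next
    }
    st1 <- ng86_sites(c1); st2 <- ng86_sites(c2)
    S <- S + (st1["syn"] + st2["syn"]) / 2
    N <- N + (st1["nonsyn"] + st2["nonsyn"]) / 2
    d <- ng86_differences(c1, c2)
    Sd <- Sd + d["syn"]; Nd <- Nd + d["nonsyn"]
    blocked <- blocked + as.integer(d["blocked"])
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ks <- jc(ps); ka <- jc(pn)
  tibble(
    gene = gene,
    s_sites = unname(S), n_sites = unname(N),
    s_diffs = unname(Sd), n_diffs = unname(Nd),
    ps = unname(ps), pn = unname(pn),
    ks = unname(ks), ka = unname(ka),
    ka_ks = if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_,
    excluded_codons = excluded,
    blocked_paths = blocked,
    saturated = is.na(ks) || is.na(ka)
  )
}
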