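# Synthetic orthologous CDS panel across taxa, with planted conservation
# states at the editing sites, to exercise cross-taxon conservation
# classification against ground truth.

#' Simulate an orthologous CDS panel with planted conservation states
#'
#' For every CDS gene carrying a planted editing site, builds an ungapped
#' orthologous alignment of the reference CDS across `n_taxa` taxa. At each
#' editing position a conservation state is planted per taxon: `"T"`
#' (editing hard-wired as genomic T), `"Edit"` (genomic C, position present
#' in the taxon's known-edit list), `"C"` (genomic C, known unedited) for
#' taxa with an edit list, or `"C?"` (genomic C, no editing information)
#' for taxa without one. One taxon additionally gets a gap over the site of
#' the first gene (the unalignable `NA` case).
#'
#' @param genome A `plast_genome`.
#' @param n_taxa Number of comparison taxa (default 8).
#' @param n_with_lists How many taxa have known-edit lists (default 6).
#' @param seed Integer seed.
#' @return List: `alignments` (per gene, named character vectors including
#'   the reference as `genome$id`), `edit_lists` (per taxon, per gene,
#'   integer CDS positions), `truth` (tibble `gene`, `t_pos`, `taxon`,
#'   `state`).
#' @export
simulate_ortholog_panel <- function(genome, n_taxa = 8L, n_with_lists = 6L,
                                    seed = genome$config$seed) {
  set.seed(child_seed(seed, 400L))
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  listed <- taxa[seq_len(n_with_lists)]
  sites <- genome$truth$edit_sites |>
    filter(.data$context == "cds") |>
    mutate(t_pos = (.data$codon - 1L) * 3L + .data$codon_pos)
  genes <- unique(sites$gene)
  alignments <- list()
  edit_lists <- setNames(
    lapply(taxa, function(t) list()), taxa
  )
  truth_rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ex <- genome$features[genome$features$gene == g, , drop = FALSE]
    ref_cds <- extract_cds(genome$sequence, ex)
    gsites <- sites[sites$gene == g, , drop = FALSE]
    rows <- setNames(rep(ref_cds, n_taxa + 1L), c(genome$id, taxa))
    for (si in seq_len(nrow(gsites))) {
      tp <- gsites$t_pos[si]
      for (tx in taxa) {
        has_list <- tx %in% listed
        state <- if (has_list) {
          sample(c("T", "Edit", "C"), 1, prob = c(0.35, 0.45, 0.20))
        } else {
          sample(c("T", "C?"), 1, prob = c(0.4, 0.6))
        }
        if (state == "T") {
          rows[tx] <- str_assign(rows[[tx]], tp, "T")
        } else if (state == "Edit") {
          edit_lists[[tx]][[g]] <- c(edit_lists[[tx]][[g]], tp)
        }
        # gene 1: first taxon gets a gap over the site (unalignable)
        if (gi == 1L && tx == taxa[1] && si == 1L) {
          rows[tx] <- str_assign(rows[[tx]], tp, "-")
          state <- NA_character_
        }
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          gene = g, t_pos = tp, taxon = tx, state = state
        )
      }
    }
    alignments[[g]] <- rows
  }
  list(
    alignments = alignments,
    edit_lists = edit_lists,
    listed_taxa = listed,
    truth = list_rbind(truth_rows)
  )
}
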