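# End-to-end orchestration on a single declarative config: synthetic-data
# generation, genome comparison, coding variation, phylogenetic input
# preparation, transcript quantification and editing analysis, with a
# checksummed output manifest. Stage toggles and all thresholds live in the
# config; a fixed seed gives identical checksums on rerun.

#' Default pipeline run configuration
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param ... Overrides for `sim` (a list passed to [sim_config()]),
#'   `stages` (named logical), or thresholds (`min_ir`, `editing` policy
#'   fields, `antisense_floor`, `fdr_alpha`, `strandedness`).
#' @return Named list of class `plast_run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("plastkit-run-"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    sim = list(),
    stages = list(compare = TRUE, variation = TRUE, phyloprep = TRUE,
                  quant = TRUE, edit = TRUE),
    min_ir = 1000L,
    editing = editing_policy(),
    antisense_floor = "auto",
    fdr_alpha = 0.05
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(sprintf("unknown run_config fields: %s",
                                 paste(bad, collapse = ", ")))
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  structure(cfg, class = c("plast_run_config", "list"))
}

#' Read / write a run configuration as YAML
#'
#' The configuration round-trips: writing and re-reading gives an identical
#' configuration.
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `read_run_config` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  do.call(run_config, c(list(seed = cfg$seed, out_dir = cfg$out_dir),
                        cfg[setdiff(names(cfg), c("seed", "out_dir"))]))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates the synthetic study defined by the config and executes the
#' enabled stages in dependency order, writing standard-format outputs
#' (FASTA, GFF3, SAM, TSV tables, PHYLIP/NEXUS) and a manifest with
#' MD5 checksums. Rerunning with the same config reproduces identical
#' checksums. Thresholds in use are echoed to the run log.
#'
#' @param config A [run_config()] or path to its YAML form.
#' @return List: `manifest` (tibble `file`, `md5`, `stage`), `results`
#'   (in-memory stage results) and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  log_path <- out("run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    inform(msg)
  }
  if (file.exists(log_path)) file.remove(log_path)
  manifest <- list()
  emit <- function(path, stage) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      file = basename(path), md5 = unname(tools::md5sum(path)), stage = stage
    )
    path
  }
  results <- list()
  run_stage <- function(name, fn) {
    logf("stage %s: start", name)
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }
  logf("seed=%d min_ir=%d editing: rate>=%.2f or >=%d edited bases, depth>=%d, bq>=%d; antisense floor=%s; FDR alpha=%.2f",
       config$seed, config$min_ir, config$editing$min_rate,
       config$editing$min_edited_bases, config$editing$min_depth,
       config$editing$min_base_quality,
       as.character(config$antisense_floor), config$fdr_alpha)

  # --- simulate -------------------------------------------------------------
  study <- run_stage("simulate", function() {
    do.call(sim_config, c(list(seed = config$seed), config$sim)) |>
      simulate_study()
  })
  results$study <- study
  genomes <- c(list(study$base), study$haplotypes)
  names(genomes) <- vapply(genomes, function(g) g$id, character(1))
  for (g in genomes) {
    emit(write_fasta(setNames(g$sequence, g$id),
                     out(sprintf("%s.fasta", g$id))), "simulate")
    emit(write_gff3(g$features, out(sprintf("%s.gff3", g$id)), seqid = g$id),
         "simulate")
  }
  emit(write_fasta(study$alignment, out("alignment.fasta")), "simulate")
  for (ind in names(study$reads)) {
    h <- study$samples$haplotype[study$samples$individual == ind]
    emit(write_sam(study$reads[[ind]]$reads, out(sprintf("%s.sam", ind)),
                   ref_name = h, ref_length = nchar(genomes[[h]]$sequence)),
         "simulate")
  }
  for (h in names(study$mito)) {
    emit(write_tsv_commented(study$mito[[h]]$inserts,
                             out(sprintf("%s-mtpt-inserts.tsv", h))),
         "simulate")
  }
  emit(write_tsv_commented(study$base$truth$ssr, out("truth-ssr.tsv")),
       "simulate")
  emit(write_tsv_commented(study$base$truth$edit_sites,
                           out("truth-editing.tsv")), "simulate")

  # --- genome comparison ----------------------------------------------------
  if (isTRUE(config$stages$compare)) {
    results$compare <- run_stage("compare", function() {
      boundaries <- lapply(genomes, function(g) {
        find_inverted_repeats(g$sequence, min_ir = config$min_ir)
      })
      dist <- plastome_distances(study$alignment)
      ssr_all <- lapply(names(genomes), function(id) {
        find_ssrs(genomes[[id]]$sequence) |> mutate(genome = id)
      }) |> list_rbind()
      poly <- ssr_polymorphism(ssr_all, study$alignment)
      list(boundaries = boundaries, distances = dist, ssr = ssr_all,
           polymorphism = poly)
    })
    b_tbl <- lapply(names(genomes), function(id) {
      results$compare$boundaries[[id]] |> mutate(genome = id)
    }) |> list_rbind()
    emit(write_tsv_commented(b_tbl, out("boundaries.tsv")), "compare")
    emit(write_tsv_commented(results$compare$distances,
                             out("distances.tsv")), "compare")
    emit(write_tsv_commented(results$compare$ssr, out("ssr.tsv")), "compare")
    emit(write_tsv_commented(
      results$compare$polymorphism |> select(-"counts"),
      out("ssr-polymorphism.tsv")
    ), "compare")
  }

  # --- coding variation -----------------------------------------------------
  if (isTRUE(config$stages$variation)) {
    results$variation <- run_stage("variation", function() {
      anns <- lapply(genomes, function(g) g$features)
      sm <- concatenate_cds(
        vapply(genomes, function(g) g$sequence, character(1)), anns
      )
      gene_names <- sm$partitions$gene
      sites <- lapply(gene_names, function(g) {
        rows <- substr(sm$matrix, sm$partitions$start[match(g, gene_names)],
                       sm$partitions$end[match(g, gene_names)])
        names(rows) <- names(sm$matrix)
        classify_segregating_sites(rows, gene = g) |> mutate(gene = g)
      }) |> list_rbind()
      summary <- summarize_genes(sites, gene_names)
      pair_ids <- utils::combn(names(genomes), 2)
      kaks <- lapply(gene_names, function(g) {
        i <- match(g, gene_names)
        rows <- substr(sm$matrix, sm$partitions$start[i], sm$partitions$end[i])
        names(rows) <- names(sm$matrix)
        lapply(seq_len(ncol(pair_ids)), function(p) {
          kaks_pairwise(rows[[pair_ids[1, p]]], rows[[pair_ids[2, p]]],
                        gene = g) |>
            mutate(genome1 = pair_ids[1, p], genome2 = pair_ids[2, p])
        }) |> list_rbind()
      }) |> list_rbind()
      list(supermatrix = sm, sites = sites, summary = summary, kaks = kaks)
    })
    emit(write_tsv_commented(results$variation$sites, out("seg-sites.tsv")),
         "variation")
    emit(write_tsv_commented(results$variation$summary,
                             out("gene-classes.tsv")), "variation")
    emit(write_tsv_commented(results$variation$kaks, out("kaks.tsv")),
         "variation")
  }

  # --- phylogenetic input preparation --------------------------------------
  if (isTRUE(config$stages$phyloprep)) {
    results$phyloprep <- run_stage("phyloprep", function() {
      b <- study$base$boundaries
      ira <- b[b$region == "IRa", ]
      noira <- remove_ira(study$alignment, ira$start, ira$end,
                          reference = study$base$id)
      cds_iv <- study$base$features |>
        filter(.data$type == "CDS") |>
        select("start", "end")
      masked <- mask_homopolymers(noira$alignment, cds = NULL, max_run = 5,
                                  reference = study$base$id)
      sic <- simple_indel_coding(noira$alignment)
      sm <- results$variation$supermatrix %||% concatenate_cds(
        vapply(genomes, function(g) g$sequence, character(1)),
        lapply(genomes, function(g) g$features)
      )
      list(no_ira = noira, masked = masked, indels = sic, supermatrix = sm)
    })
    emit(write_fasta(results$phyloprep$masked$masked_alignment,
                     out("masked-alignment.fasta")), "phyloprep")
    emit(write_tsv_commented(results$phyloprep$masked$mask,
                             out("mask-log.tsv"),
                             comment = "# columns of the IRa-removed alignment"),
         "phyloprep")
    emit(write_phylip(results$phyloprep$supermatrix, out("cds.phy")),
         "phyloprep")
    emit(write_partitions(results$phyloprep$supermatrix,
                          out("cds-partitions.txt")), "phyloprep")
    emit(write_nexus(results$phyloprep$masked$masked_alignment,
                     results$phyloprep$indels, out("plastome.nex")),
         "phyloprep")
  }

  # --- transcript quantification -------------------------------------------
  scfg <- study$config
  if (isTRUE(config$stages$quant) || isTRUE(config$stages$edit)) {
    results$quant <- run_stage("quant", function() {
      per_ind <- list()
      for (i in seq_len(nrow(study$samples))) {
        ind <- study$samples$individual[i]
        h <- study$samples$haplotype[i]
        genome <- genomes[[h]]
        sep <- separate_strands(study$reads[[ind]]$reads,
                                convention = scfg$strandedness)
        stranded <- bind_strand_sets(sep)
        flt <- filter_mtpt_reads(
          stranded, study$mito[[h]]$inserts, genome$sequence,
          min_base_quality = config$editing$min_base_quality
        )
        cov <- depth_of_coverage(flt$retained, nchar(genome$sequence))
        fc <- feature_coverage(cov, genome$features)
        tpm <- compute_tpm(fc |> filter(.data$type == "CDS"))
        anti <- detect_antisense(cov, genome$features,
                                 floor = config$antisense_floor)
        per_ind[[ind]] <- list(
          sep = sep, filtered = flt, coverage = cov, feature_coverage = fc,
          tpm = tpm, antisense = anti,
          accounting = tibble(
            individual = ind,
            input = nrow(study$reads[[ind]]$reads),
            plus = sum(flt$retained$strand == "+"),
            minus = sum(flt$retained$strand == "-"),
            unassigned = nrow(sep$unassigned),
            mtpt_discarded = nrow(flt$discarded)
          )
        )
      }
      tpm_long <- lapply(names(per_ind), function(ind) {
        per_ind[[ind]]$tpm |> mutate(individual = ind)
      }) |> list_rbind() |>
        left_join(study$samples, by = "individual")
      de <- list()
      for (h in unique(study$samples$haplotype)) {
        de[[h]] <- compare_groups(tpm_long |> filter(.data$haplotype == h),
                                  by = "sex", alpha = config$fdr_alpha)
      }
      list(per_individual = per_ind, tpm = tpm_long, sex_comparison = de)
    })
    acct <- lapply(results$quant$per_individual, function(x) x$accounting) |>
      list_rbind()
    emit(write_tsv_commented(acct, out("read-accounting.tsv")), "quant")
    emit(write_tsv_commented(
      results$quant$tpm |> select("individual", "haplotype", "sex",
                                  "feature", "sense", "tpm"),
      out("tpm.tsv")
    ), "quant")
    anti_tbl <- lapply(names(results$quant$per_individual), function(ind) {
      results$quant$per_individual[[ind]]$antisense |>
        mutate(individual = ind)
    }) |> list_rbind()
    emit(write_tsv_commented(anti_tbl, out("antisense.tsv")), "quant")
    for (h in names(results$quant$sex_comparison)) {
      emit(write_tsv_commented(tidy(results$quant$sex_comparison[[h]]),
                               out(sprintf("de-sex-%s.tsv", h))), "quant")
    }
    for (ind in names(results$quant$per_individual)) {
      emit(write_bedgraph(results$quant$per_individual[[ind]]$coverage,
                          out(sprintf("%s-coverage.bedgraph", ind)),
                          name = ind), "quant")
    }
  }

  # --- editing --------------------------------------------------------------
  if (isTRUE(config$stages$edit)) {
    results$edit <- run_stage("edit", function() {
      pileups <- lapply(names(results$quant$per_individual), function(ind) {
        h <- study$samples$haplotype[study$samples$individual == ind]
        build_pileup(results$quant$per_individual[[ind]]$filtered$retained,
                     genomes[[h]]$sequence,
                     min_base_quality = config$editing$min_base_quality) |>
          mutate(individual = ind, haplotype = h)
      })
      names(pileups) <- names(results$quant$per_individual)
      calls <- list()
      annotated <- list()
      for (h in unique(study$samples$haplotype)) {
        hp <- list_rbind(pileups[study$samples$individual[
          study$samples$haplotype == h]])
        called <- call_editing_sites(hp, policy = config$editing)
        site_pos <- called$sites |> distinct(.data$pos, .data$strand)
        ann <- annotate_editing_effects(site_pos, genomes[[h]]$features,
                                        genomes[[h]]$sequence,
                                        utr = scfg$utr_length)
        calls[[h]] <- called
        annotated[[h]] <- ann
      }
      # cross-taxon conservation of the called CDS sites (haplotype 1 panel)
      h1 <- names(genomes)[2]
      panel <- simulate_ortholog_panel(genomes[[h1]])
      cons <- list()
      ann1 <- annotated[[h1]] |> filter(.data$context == "cds")
      for (i in seq_len(nrow(ann1))) {
        row <- ann1[i, ] |>
          mutate(t_pos = (.data$codon - 1L) * 3L + .data$codon_pos)
        g <- row$gene
        if (!g %in% names(panel$alignments)) next
        lists_g <- lapply(panel$edit_lists[panel$listed_taxa],
                          function(l) l[[g]] %||% integer())
        cons[[length(cons) + 1L]] <- classify_conservation(
          row, panel$alignments[[g]], reference_taxon = h1,
          edit_lists = lists_g
        ) |> mutate(pos = row$pos, strand = row$strand, gene = g)
      }
      conservation <- if (length(cons)) list_rbind(cons) else NULL
      # sex comparison within each haplotype
      sexcmp <- list()
      for (h in unique(study$samples$haplotype)) {
        s <- calls[[h]]$sites |>
          left_join(study$samples |> select("individual", "sex"),
                    by = "individual")
        sexcmp[[h]] <- compare_editing(s, by = "sex",
                                       alpha = config$fdr_alpha)
      }
      # haplotype comparison at homologous positions: map each haplotype's
      # called sites to ancestral coordinates through the planted edits,
      # look rates up in both haplotypes (even where below threshold), and
      # run the two-proportion comparison
      haps <- unique(study$samples$haplotype)
      hapcmp <- NULL
      if (length(haps) == 2) {
        n_base <- nchar(study$base$sequence)
        base2hap <- lapply(haps, function(h) {
          lift_positions(genomes[[h]]$truth$divergence$edits,
                         seq_len(n_base))
        })
        names(base2hap) <- haps
        union_base <- lapply(haps, function(h) {
          calls[[h]]$sites |>
            distinct(.data$pos, .data$strand) |>
            mutate(base_pos = match(.data$pos, base2hap[[h]])) |>
            filter(!is.na(.data$base_pos))
        }) |>
          list_rbind() |>
          distinct(.data$base_pos, .data$strand)
        rates <- lapply(haps, function(h) {
          hp <- list_rbind(pileups[study$samples$individual[
            study$samples$haplotype == h]])
          editing_rates_at(
            hp,
            union_base |>
              transmute(pos = base2hap[[h]][.data$base_pos],
                        strand = .data$strand)
          ) |>
            mutate(haplotype = h,
                   base_pos = union_base$base_pos[
                     match(.data$pos, base2hap[[h]][union_base$base_pos])])
        }) |> list_rbind()
        hapcmp <- rates |>
          mutate(pos = .data$base_pos) |>
          compare_editing(by = "haplotype", alpha = config$fdr_alpha)
      }
      list(calls = calls, annotated = annotated, sex_comparison = sexcmp,
           haplotype_comparison = hapcmp,
           conservation = conservation, ortho_panel = panel)
    })
    for (h in names(results$edit$calls)) {
      emit(write_tsv_commented(
        results$edit$calls[[h]]$sites,
        out(sprintf("editing-sites-%s.tsv", h)),
        comment = "# CHROM-free site table; POS 1-based; REF=C on the transcribed strand"
      ), "edit")
      emit(write_tsv_commented(results$edit$annotated[[h]],
                               out(sprintf("editing-effects-%s.tsv", h))),
           "edit")
      emit(write_tsv_commented(tidy(results$edit$sex_comparison[[h]]),
                               out(sprintf("editing-sex-%s.tsv", h))),
           "edit")
    }
    if (!is.null(results$edit$haplotype_comparison)) {
      emit(write_tsv_commented(
        tidy(results$edit$haplotype_comparison),
        out("editing-haplotype.tsv"),
        comment = "# pos: ancestral (REF) coordinates, 1-based"
      ), "edit")
    }
    if (!is.null(results$edit$conservation)) {
      emit(write_tsv_commented(results$edit$conservation,
                               out("editing-conservation.tsv")), "edit")
    }
  }

  manifest <- list_rbind(manifest)
  emit_manifest <- out("manifest.tsv")
  readr::write_tsv(manifest, emit_manifest)
  logf("pipeline complete: %d files", nrow(manifest))
  list(manifest = manifest, results = results, config = config)
}

#' Write strand-specific coverage as bedGraph
#'
#' bedGraph uses 0-based half-open intervals (the only 0-based output;
#' stated in the track header). One track per strand, minus-strand depths
#' negated, as is conventional for stranded coverage browsers.
#'
#' @param coverage A [depth_of_coverage()] result.
#' @param path Output path.
#' @param name Track name prefix.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path, name = "sample") {
  lines <- c(sprintf(
    "# bedGraph: 0-based, half-open intervals; sample %s", name
  ))
  for (st in c("+", "-")) {
    v <- coverage$depth[coverage$strand == st]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    sign <- if (st == "+") 1 else -1
    lines <- c(
      lines,
      sprintf("track type=bedGraph name=\"%s %s strand\"", name, st),
      sprintf("ref\t%d\t%d\t%d", starts[keep] - 1L, ends[keep],
              sign * r$values[keep])
    )
  }
  readr::write_lines(lines, path)
  invisible(path)
}
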