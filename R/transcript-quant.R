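# Strand separation of paired-end alignments, MTPT read filtering, per-base
# depth of coverage, per-feature TPM, antisense detection and group
# comparison. Internally positions are the 1-based reference coordinates of
# the SAM records; all emitted tables are 1-based inclusive.

# decode the SAM flag bits used here
flag_bits <- function(flag) {
  tibble(
    paired = bitwAnd(flag, 1L) > 0L,
    proper = bitwAnd(flag, 2L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    mate_reverse = bitwAnd(flag, 32L) > 0L,
    first = bitwAnd(flag, 64L) > 0L,
    second = bitwAnd(flag, 128L) > 0L
  )
}

# per-unique-cigar decomposition: reference width and M-segment offsets
cigar_layout <- function(cigars) {
  uc <- unique(cigars)
  lay <- lapply(uc, function(cg) {
    if (grepl("^[0-9]+M$", cg)) {
      w <- as.integer(sub("M", "", cg))
      return(list(ref_width = w,
                  m = tibble(ref_off = 0L, read_off = 0L, len = w)))
    }
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    kinds <- sub("[0-9]+", "", ops)
    ref_off <- 0L; read_off <- 0L
    m <- list()
    for (i in seq_along(ops)) {
      k <- kinds[i]; l <- lens[i]
      if (k %in% c("M", "=", "X")) {
        m[[length(m) + 1L]] <- tibble(ref_off = ref_off,
                                      read_off = read_off, len = l)
        ref_off <- ref_off + l; read_off <- read_off + l
      } else if (k %in% c("D", "N")) {
        ref_off <- ref_off + l
      } else if (k %in% c("I", "S")) {
        read_off <- read_off + l
      }
    }
    list(ref_width = ref_off, m = list_rbind(m))
  })
  names(lay) <- uc
  lay
}

# reference span width of each read
read_ref_width <- function(reads) {
  lay <- cigar_layout(reads$cigar)
  vapply(reads$cigar, function(cg) lay[[cg]]$ref_width, integer(1),
         USE.NAMES = FALSE)
}

#' Separate paired-end alignments by transcriptional strand
#'
#' Assigns each properly-paired fragment to the transcriptional strand
#' implied by the library convention. Under `"fr-firststrand"` (dUTP-style)
#' read 1 aligns antisense to the transcript, so a reverse-mapped read 1 (or
#' forward-mapped read 2) indicates a plus-strand transcript;
#' `"fr-secondstrand"` is the inverse. Records that are not properly paired,
#' or whose mate-strand flags are inconsistent within a pair, go to
#' `unassigned` with a reason code. The partition is exhaustive and
#' disjoint.
#'
#' @param reads Read tibble (SAM columns).
#' @param convention `"fr-firststrand"` or `"fr-secondstrand"`.
#' @return List with tibbles `plus`, `minus`, `unassigned` (extra column
#'   `reason`).
#' @export
separate_strands <- function(reads,
                             convention = c("fr-firststrand",
                                            "fr-secondstrand")) {
  convention <- match.arg(convention)
  fb <- flag_bits(reads$flag)
  improper <- !(fb$paired & fb$proper)
  # within-pair consistency: each qname must have one first + one second
  # mate on opposite strands, and each record's mate_reverse bit must match
  o <- order(reads$qname)
  qn <- reads$qname[o]
  run_id <- cumsum(c(TRUE, qn[-1] != qn[-length(qn)]))
  run_len <- tabulate(run_id)[run_id]
  ok_sorted <- rep(FALSE, length(o))
  two <- run_len == 2L
  if (any(two)) {
    i <- which(two)
    # partner of each member of a 2-run: the other row of the run
    is_first_of_run <- c(TRUE, run_id[-1] != run_id[-length(run_id)])[i]
    partner <- ifelse(is_first_of_run, i + 1L, i - 1L)
    ok_sorted[i] <-
      (fb$first[o][i] != fb$first[o][partner]) &
      (fb$reverse[o][i] != fb$reverse[o][partner]) &
      (fb$mate_reverse[o][i] == fb$reverse[o][partner])
  }
  pair_ok <- logical(length(o))
  pair_ok[o] <- ok_sorted
  unassigned_why <- dplyr::case_when(
    improper ~ "not-properly-paired",
    !pair_ok ~ "inconsistent-mate-flags",
    TRUE ~ NA_character_
  )
  assignable <- is.na(unassigned_why)
  # read-1-reverse (or read-2-forward) => plus under fr-firststrand
  sense_bit <- ifelse(fb$first, fb$reverse, !fb$reverse)
  if (convention == "fr-secondstrand") sense_bit <- !sense_bit
  strand <- ifelse(sense_bit, "+", "-")
  list(
    plus = reads[assignable & strand == "+", , drop = FALSE],
    minus = reads[assignable & strand == "-", , drop = FALSE],
    unassigned = reads[!assignable, , drop = FALSE] |>
      mutate(reason = unassigned_why[!assignable])
  )
}

# bind a separate_strands() result into one tibble with a strand column
bind_strand_sets <- function(sep) {
  bind_rows(
    sep$plus |> mutate(strand = "+"),
    sep$minus |> mutate(strand = "-")
  )
}

#' Per-read mismatches against the reference
#'
#' CIGAR-aware comparison of aligned read bases with the reference
#' (M/=/X segments; insertions and clips skipped, deletions contribute
#' nothing).
#'
#' @param reads Read tibble.
#' @param reference Reference sequence string.
#' @return Tibble `row` (index into `reads`), `pos` (reference), `ref`,
#'   `alt`, `qual` (Phred score of the read base).
#' @export
read_mismatches <- function(reads, reference) {
  if (!nrow(reads)) {
    return(tibble(row = integer(), pos = integer(), ref = character(),
                  alt = character(), qual = integer()))
  }
  lay <- cigar_layout(reads$cigar)
  out <- list()
  simple <- grepl("^[0-9]+M$", reads$cigar)
  # fast path: ungapped reads, vectorized reference compare
  if (any(simple)) {
    idx <- which(simple)
    w <- vapply(reads$cigar[idx], function(cg) lay[[cg]]$ref_width,
                integer(1), USE.NAMES = FALSE)
    refs <- substring(reference, reads$pos[idx], reads$pos[idx] + w - 1L)
    differ <- idx[reads$seq[idx] != refs]
    if (length(differ)) {
      wd <- nchar(reads$seq[differ])
      ds <- strsplit(reads$seq[differ], "", fixed = TRUE)
      dr <- strsplit(substring(reference, reads$pos[differ],
                               reads$pos[differ] + wd - 1L),
                     "", fixed = TRUE)
      offs <- purrr::map2(ds, dr, function(a, b) which(a != b))
      n_off <- lengths(offs)
      ridx <- rep(seq_along(differ), n_off)
      off_flat <- unlist(offs)
      out[[length(out) + 1L]] <- tibble(
        row = differ[ridx],
        pos = reads$pos[differ][ridx] + off_flat - 1L,
        ref = unlist(purrr::map2(dr, offs, `[`)),
        alt = unlist(purrr::map2(ds, offs, `[`)),
        qual = utf8ToInt(paste(unlist(purrr::map2(
          strsplit(reads$qual[differ], "", fixed = TRUE), offs, `[`
        )), collapse = "")) - 33L
      )
    }
  }
  for (r in which(!simple)) {
    l <- lay[[reads$cigar[r]]]
    sc <- seq_chars(reads$seq[r])
    qc <- utf8ToInt(reads$qual[r]) - 33L
    for (s in seq_len(nrow(l$m))) {
      seg <- l$m[s, ]
      ref_at <- reads$pos[r] + seg$ref_off + seq_len(seg$len) - 1L
      read_at <- seg$read_off + seq_len(seg$len)
      rc <- seq_chars(substring(reference, min(ref_at), max(ref_at)))
      diff <- which(sc[read_at] != rc)
      if (length(diff)) {
        out[[length(out) + 1L]] <- tibble(
          row = r, pos = ref_at[diff], ref = rc[diff],
          alt = sc[read_at][diff], qual = qc[read_at][diff]
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(row = integer(), pos = integer(), ref = character(),
                  alt = character(), qual = integer()))
  }
  list_rbind(out)
}

#' Filter reads derived from mitochondrial plastid-like inserts
#'
#' Within the insert-homologous intervals, a read is discarded if and only
#' if it carries at least one high-quality mismatch to the plastid
#' reference that is not a candidate editing change (C->T on plus-strand
#' assignments, G->A on minus). Reads outside the intervals are untouched.
#'
#' @param reads Read tibble with a `strand` column (`"+"`/`"-"`), e.g. from
#'   [bind_strand_sets()] applied to [separate_strands()] output.
#' @param inserts Insert interval table with columns `plastid_start`,
#'   `plastid_end` (1-based inclusive plastid coordinates).
#' @param reference Plastid reference sequence.
#' @param min_base_quality Mismatches below this Phred score are ignored
#'   (default 20).
#' @return List with tibbles `retained` and `discarded`.
#' @export
filter_mtpt_reads <- function(reads, inserts, reference,
                              min_base_quality = 20) {
  if (is.null(inserts) || !nrow(inserts)) {
    return(list(retained = reads, discarded = reads[0, , drop = FALSE]))
  }
  if (!all(c("plastid_start", "plastid_end") %in% names(inserts))) {
    abort("malformed insert table: need plastid_start/plastid_end columns")
  }
  if (!"strand" %in% names(reads)) {
    abort("reads must carry a strand column (run separate_strands first)")
  }
  w <- read_ref_width(reads)
  span_end <- reads$pos + w - 1L
  in_insert <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(inserts))) {
    in_insert <- in_insert |
      (reads$pos <= inserts$plastid_end[i] &
         span_end >= inserts$plastid_start[i])
  }
  sub <- which(in_insert)
  if (!length(sub)) {
    return(list(retained = reads, discarded = reads[0, , drop = FALSE]))
  }
  mm <- read_mismatches(reads[sub, , drop = FALSE], reference)
  mm <- mm |>
    filter(.data$qual >= min_base_quality) |>
    mutate(
      strand = reads$strand[sub][.data$row],
      candidate_edit = (.data$strand == "+" & .data$ref == "C" &
                          .data$alt == "T") |
        (.data$strand == "-" & .data$ref == "G" & .data$alt == "A")
    )
  bad_rows <- unique(mm$row[!mm$candidate_edit])
  discard <- sub[bad_rows]
  list(
    retained = if (length(discard)) reads[-discard, , drop = FALSE] else reads,
    discarded = reads[discard, , drop = FALSE]
  )
}

#' Per-base, per-strand depth of coverage
#'
#' Counts aligned bases per reference position (CIGAR-aware: M/=/X consume
#' reference and add depth, D/N consume reference without depth).
#'
#' @param reads Read tibble with a `strand` column.
#' @param ref_length Reference length.
#' @return A `plast_coverage` tibble: `pos`, `strand`, `depth` over the full
#'   1..`ref_length` x {+,-} grid.
#' @export
depth_of_coverage <- function(reads, ref_length) {
  if (nrow(reads) &&
      any(reads$pos + read_ref_width(reads) - 1L > ref_length)) {
    abort("read beyond reference end; resolve circular wrap before coverage")
  }
  one_strand <- function(sub) {
    if (!nrow(sub)) return(integer(ref_length))
    lay <- cigar_layout(sub$cigar)
    # expand M segments; single IRanges coverage call
    segs <- lapply(unique(sub$cigar), function(cg) {
      rows <- which(sub$cigar == cg)
      m <- lay[[cg]]$m
      tibble(
        start = rep(sub$pos[rows], each = nrow(m)) + rep(m$ref_off, length(rows)),
        width = rep(m$len, length(rows))
      )
    })
    segs <- list_rbind(segs)
    cov <- IRanges::coverage(
      IRanges::IRanges(start = segs$start, width = segs$width),
      width = ref_length
    )
    as.integer(cov)
  }
  out <- bind_rows(
    tibble(pos = seq_len(ref_length), strand = "+",
           depth = one_strand(reads[reads$strand == "+", , drop = FALSE])),
    tibble(pos = seq_len(ref_length), strand = "-",
           depth = one_strand(reads[reads$strand == "-", , drop = FALSE]))
  )
  class(out) <- c("plast_coverage", class(out))
  attr(out, "ref_length") <- ref_length
  out
}

#' Per-feature mean depth of coverage
#'
#' Averages per-base depth over each gene's span (all exons and introns of
#' the primary transcript), on the gene's own strand (`sense`), the
#' opposite strand (`antisense`) and regardless of strand (`unstranded`).
#'
#' @param coverage A [depth_of_coverage()] result.
#' @param features Feature tibble.
#' @return Tibble `feature`, `type`, `strand`, `length`, `sense`,
#'   `antisense`, `unstranded`.
#' @export
feature_coverage <- function(coverage, features) {
  plus <- coverage$depth[coverage$strand == "+"]
  minus <- coverage$depth[coverage$strand == "-"]
  g <- features |>
    group_by(.data$gene) |>
    summarise(type = first(.data$type), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  sense <- numeric(nrow(g)); anti <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    span <- g$start[i]:g$end[i]
    own <- if (g$strand[i] == "+") plus else minus
    opp <- if (g$strand[i] == "+") minus else plus
    sense[i] <- mean(own[span])
    anti[i] <- mean(opp[span])
  }
  g |>
    mutate(length = .data$end - .data$start + 1L,
           sense = sense, antisense = anti,
           unstranded = sense + anti) |>
    rename(feature = "gene") |>
    select("feature", "type", "strand", "length", "sense", "antisense",
           "unstranded")
}

#' Transcripts-per-million from per-feature mean depth
#'
#' Mean per-base depth is already length-normalized, so the TPM of feature
#' i is simply its mean depth divided by the sum over quantified features,
#' times 1e6. TPM sums to 1e6 by construction.
#'
#' @param means Tibble with a `feature` column and a mean-depth column.
#' @param depth_col Name of the mean-depth column (default `"sense"`).
#' @return `means` with an added `tpm` column.
#' @export
compute_tpm <- function(means, depth_col = "sense") {
  rates <- means[[depth_col]]
  if (all(rates == 0)) abort("all feature depths are zero; TPM undefined")
  means |> mutate(tpm = rates / sum(rates) * 1e6)
}

#' Detect antisense transcripts from strand-specific coverage
#'
#' Reports maximal intervals longer than `min_length` where depth on one
#' strand stays at or above the floor and no same-strand annotated feature
#' is overlapped (so the interval is antisense to every overlapped
#' feature). In `floor = "auto"` mode the floor is the smallest per-gene
#' sense mean depth among protein-coding genes in the same sample, the
#' depth that corresponds to the TPM of the least expressed protein-coding
#' gene.
#'
#' @param coverage A [depth_of_coverage()] result.
#' @param features Feature tibble.
#' @param min_length Minimum call length in nt (calls must exceed it).
#' @param floor `"auto"` or a fixed depth.
#' @param merge_gap Above-floor runs separated by at most this many bases
#'   are merged before the length filter (default 100). Paired-end coverage
#'   of a short transcript dips in the fragment interior that neither read
#'   reaches; merging bridges that sequencing artefact.
#' @return Tibble `start`, `end`, `length`, `strand`, `mean_depth`,
#'   `tpm_equivalent`, `features_opposite` (comma-separated overlapped
#'   features).
#' @export
detect_antisense <- function(coverage, features, min_length = 100,
                             floor = "auto", merge_gap = 100) {
  fc <- feature_coverage(coverage, features)
  cds <- fc |> filter(.data$type == "CDS")
  floor_val <- if (identical(floor, "auto")) min(cds$sense) else as.numeric(floor)
  rate_sum <- sum(cds$sense)
  gene_iv <- features |>
    group_by(.data$gene) |>
    summarise(strand = first(.data$strand), start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  calls <- list()
  for (st in c("+", "-")) {
    v <- coverage$depth[coverage$strand == st]
    r <- rle(v >= floor_val)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_iv <- tibble(start = starts[r$values], end = ends[r$values])
    if (nrow(run_iv) > 1) {
      merged <- IRanges::reduce(
        IRanges::IRanges(run_iv$start, run_iv$end),
        min.gapwidth = merge_gap + 1L
      )
      run_iv <- tibble(start = IRanges::start(merged),
                       end = IRanges::end(merged))
    }
    for (h in which(run_iv$end - run_iv$start + 1L > min_length)) {
      iv <- c(run_iv$start[h], run_iv$end[h])
      ov <- gene_iv |> filter(.data$start <= iv[2], .data$end >= iv[1])
      if (any(ov$strand == st)) next  # sense transcription, not antisense
      calls[[length(calls) + 1L]] <- tibble(
        start = iv[1], end = iv[2], length = iv[2] - iv[1] + 1L,
        strand = st,
        mean_depth = mean(v[iv[1]:iv[2]]),
        tpm_equivalent = mean(v[iv[1]:iv[2]]) / rate_sum * 1e6,
        features_opposite = paste(ov$gene, collapse = ",")
      )
    }
  }
  if (!length(calls)) {
    return(tibble(start = integer(), end = integer(), length = integer(),
                  strand = character(), mean_depth = double(),
                  tpm_equivalent = double(), features_opposite = character()))
  }
  list_rbind(calls) |> arrange(.data$start)
}

#' Compare per-feature expression between groups
#'
#' Two-sided Welch t-test on log2(TPM + 1) per feature, with
#' Benjamini-Hochberg adjustment across features.
#'
#' @param tpm Long tibble with columns `individual`, `feature`, `tpm` plus
#'   the grouping column.
#' @param by Grouping column name (e.g. `"sex"` or `"haplotype"`).
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @return A `plast_group_test` tibble: `feature`, `group1`, `group2`,
#'   `estimate` (log2 fold change group2 vs group1), `p_value`, `p_adj`,
#'   `significant`.
#' @export
compare_groups <- function(tpm, by, alpha = 0.05) {
  groups <- sort(unique(tpm[[by]]))
  if (length(groups) != 2) abort("exactly two groups are required")
  sizes <- tpm |> distinct(.data$individual, .data[[by]]) |> count(.data[[by]])
  if (any(sizes$n < 2)) abort("each group needs at least 2 replicates")
  res <- tpm |>
    mutate(logtpm = log2(.data$tpm + 1)) |>
    group_by(.data$feature) |>
    summarise(
      estimate = mean(.data$logtpm[.data[[by]] == groups[2]]) -
        mean(.data$logtpm[.data[[by]] == groups[1]]),
      p_value = tryCatch(
        t.test(.data$logtpm[.data[[by]] == groups[2]],
               .data$logtpm[.data[[by]] == groups[1]])$p.value,
        error = function(e) 1  # zero variance in both groups
      ),
      .groups = "drop"
    ) |>
    mutate(
      group1 = groups[1], group2 = groups[2],
      p_adj = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_adj < alpha
    ) |>
    select("feature", "group1", "group2", "estimate", "p_value", "p_adj",
           "significant")
  class(res) <- c("plast_group_test", class(res))
  attr(res, "by") <- by
  attr(res, "alpha") <- alpha
  res
}
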