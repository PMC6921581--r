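# Whole-plastome structural and repeat analysis: inverted-repeat boundary
# detection, pairwise substitution/indel distances on alignments, SSR
# discovery and cross-genome SSR polymorphism.

#' Detect the inverted-repeat pair and quadripartite boundaries
#'
#' Finds the longest pair of disjoint intervals whose sequences are exact
#' reverse complements of each other (the IRa/IRb pair of a plastome) and
#' derives the implied single-copy regions. The longer single-copy region is
#' labelled LSC, the shorter SSC; the repeat that follows the LSC in circular
#' order is labelled IRb, matching the conventional LSC-IRb-SSC-IRa layout.
#' Ties on repeat length are broken by the leftmost start.
#'
#' @param sequence A single DNA string (linearized circular plastome).
#' @param min_ir Minimum repeat length to consider, in bp (default 1000).
#' @param seed_k Seed k-mer size used for matching; any true repeat of at
#'   least `min_ir` bp contains a seed, so this only affects speed.
#' @return A tibble with columns `region` (LSC/IRb/SSC/IRa), `start`, `end`,
#'   `length` (1-based inclusive). If no inverted repeat of at least `min_ir`
#'   bp exists, a single row with `region = "single-copy"` spanning the whole
#'   sequence is returned.
#' @examples
#' ir <- paste(sample(c("A","C","G","T"), 1500, TRUE), collapse = "")
#' g <- paste0(paste(sample(c("A","C","G","T"), 4000, TRUE), collapse = ""),
#'             ir,
#'             paste(sample(c("A","C","G","T"), 2000, TRUE), collapse = ""),
#'             revcomp(ir))
#' find_inverted_repeats(g, min_ir = 1000)
#' @export
find_inverted_repeats <- function(sequence, min_ir = 1000, seed_k = 32L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  no_ir <- tibble(
    region = "single-copy", start = 1L, end = n, length = n
  )
  if (n < 2L * min_ir + 2L) {
    return(no_ir)
  }
  k <- min(as.integer(seed_k), as.integer(min_ir))
  rc <- revcomp(sequence)
  starts <- seq_len(n - k + 1L)
  km_f <- substring(sequence, starts, starts + k - 1L)
  km_r <- substring(rc, starts, starts + k - 1L)

  # join seeds; cap highly repetitive k-mers to bound the pair explosion
  tf <- tibble(i = starts, kmer = km_f)
  tr <- tibble(j = starts, kmer = km_r)
  counts_f <- table(tf$kmer)
  busy <- names(counts_f)[counts_f > 25]
  if (length(busy)) {
    tf <- filter(tf, !.data$kmer %in% busy)
    tr <- filter(tr, !.data$kmer %in% busy)
  }
  hits <- inner_join(tf, tr, by = "kmer", relationship = "many-to-many")
  if (nrow(hits) == 0) return(no_ir)

  # maximal exact matches = maximal runs of consecutive seed hits on a diagonal
  hits <- hits |>
    mutate(diag = .data$i - .data$j) |>
    arrange(.data$diag, .data$i) |>
    mutate(new_run = .data$diag != lag(.data$diag, default = NA_integer_) |
             .data$i != lag(.data$i, default = NA_integer_) + 1L,
           run = cumsum(replace_na(.data$new_run, TRUE)))
  runs <- hits |>
    group_by(.data$run) |>
    summarise(i0 = min(.data$i), i1 = max(.data$i), j0 = min(.data$j),
              .groups = "drop") |>
    mutate(len = .data$i1 - .data$i0 + k)

  cand <- runs |>
    filter(.data$len >= min_ir) |>
    mutate(
      start1 = .data$i0, end1 = .data$i0 + .data$len - 1L,
      # map the reverse-complement coordinates back onto the forward strand
      start2 = n - (.data$j0 + .data$len - 1L) + 1L,
      end2 = n - .data$j0 + 1L
    ) |>
    filter(.data$start1 < .data$start2, .data$end1 < .data$start2) |>
    arrange(dplyr::desc(.data$len), .data$start1, .data$start2)
  if (nrow(cand) == 0) return(no_ir)

  best <- cand[1, ]
  r1 <- c(best$start1, best$end1)
  r2 <- c(best$start2, best$end2)
  # single-copy gaps between the repeats (gap2 wraps around the origin)
  gap1 <- c(r1[2] + 1L, r2[1] - 1L)
  gap1_len <- max(0L, gap1[2] - gap1[1] + 1L)
  gap2_len <- (r1[1] - 1L) + (n - r2[2])
  lsc_is_gap1 <- gap1_len >= gap2_len

  gap_rows <- function(region, wrap_first, wrap_second, inner) {
    if (!is.null(inner)) {
      tibble(region = region, start = inner[1], end = inner[2],
             length = inner[2] - inner[1] + 1L)
    } else {
      parts <- list()
      if (r2[2] < n) parts <- c(parts, list(c(r2[2] + 1L, n)))
      if (r1[1] > 1L) parts <- c(parts, list(c(1L, r1[1] - 1L)))
      if (!length(parts)) {
        tibble(region = region, start = integer(), end = integer(),
               length = integer())
      } else {
        bind_rows(lapply(parts, function(p) {
          tibble(region = region, start = p[1], end = p[2],
                 length = p[2] - p[1] + 1L)
        }))
      }
    }
  }

  if (lsc_is_gap1) {
    lsc <- gap_rows("LSC", inner = gap1)
    ssc <- gap_rows("SSC", inner = NULL)
    irb <- tibble(region = "IRb", start = r2[1], end = r2[2])  # follows LSC
    ira <- tibble(region = "IRa", start = r1[1], end = r1[2])
  } else {
    lsc <- gap_rows("LSC", inner = NULL)
    ssc <- gap_rows("SSC", inner = gap1)
    irb <- tibble(region = "IRb", start = r1[1], end = r1[2])  # follows LSC
    ira <- tibble(region = "IRa", start = r2[1], end = r2[2])
  }
  bind_rows(lsc, irb, ssc, ira) |>
    mutate(length = .data$end - .data$start + 1L) |>
    arrange(.data$start)
}

#' Count substitutions between two aligned sequences
#'
#' Counts alignment columns where both rows carry unambiguous, non-gap bases
#' that differ. Columns containing a gap or an N in either row are skipped,
#' as in SNP distance matrices computed from whole-genome alignments.
#'
#' @param a,b Gapped aligned sequences of equal length.
#' @return Integer substitution count.
#' @examples
#' count_substitutions("ACGT", "ACGA")  # 1
#' count_substitutions("AC-T", "ACGT")  # 0 (gap column excluded)
#' @export
count_substitutions <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("aligned sequences must have equal (gapped) length")
  }
  ca <- seq_chars(toupper(a))
  cb <- seq_chars(toupper(b))
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  sum(ok & ca != cb)
}

#' Count indels between two aligned sequences
#'
#' Under the `"indel"` model every column gapped in exactly one row counts
#' one; under `"indelblock"` each maximal run of such columns counts one
#' (one event per contiguous gap block).
#'
#' @param a,b Gapped aligned sequences of equal length.
#' @param model `"indel"` or `"indelblock"`.
#' @return Integer indel count.
#' @examples
#' count_indels("A--T", "ACGT", model = "indel")       # 2
#' count_indels("A--T", "ACGT", model = "indelblock")  # 1
#' @export
count_indels <- function(a, b, model = c("indelblock", "indel")) {
  model <- match.arg(model)
  if (nchar(a) != nchar(b)) {
    abort("aligned sequences must have equal (gapped) length")
  }
  ga <- seq_chars(a) == "-"
  gb <- seq_chars(b) == "-"
  one <- xor(ga, gb)
  if (model == "indel") {
    sum(one)
  } else {
    r <- rle(one)
    sum(r$values)
  }
}

#' Pairwise distance table over a multiple alignment
#'
#' @param alignment Named character vector of gapped rows of equal length.
#' @return Tibble with one row per unordered genome pair: `genome1`,
#'   `genome2`, `substitutions`, `indel`, `indelblock`.
#' @export
plastome_distances <- function(alignment) {
  stopifnot(length(alignment) >= 2, !is.null(names(alignment)))
  ids <- names(alignment)
  pairs <- utils::combn(ids, 2)
  purrr::map(seq_len(ncol(pairs)), function(p) {
    g1 <- pairs[1, p]; g2 <- pairs[2, p]
    tibble(
      genome1 = g1, genome2 = g2,
      substitutions = count_substitutions(alignment[[g1]], alignment[[g2]]),
      indel = count_indels(alignment[[g1]], alignment[[g2]], "indel"),
      indelblock = count_indels(alignment[[g1]], alignment[[g2]], "indelblock")
    )
  }) |> list_rbind()
}
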