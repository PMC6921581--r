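# Microsatellite (SSR) discovery with MISA-style thresholds and cross-genome
# SSR polymorphism through alignment coordinates.

#' Default SSR reporting thresholds
#'
#' Mononucleotide tracts must be longer than five nucleotides (total length
#' at least 6); di- and trinucleotide loci need at least 4 repeat units;
#' tetra-, penta- and hexanucleotide loci at least 3 units.
#'
#' @return A list with `mono_min_length` and `min_units` (named by unit size
#'   2..6).
#' @export
ssr_thresholds <- function() {
  list(
    mono_min_length = 6L,
    min_units = c(`2` = 4L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
  )
}

# smallest period of a string (u if not periodic)
smallest_period <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L &&
        s == paste(rep(substr(s, 1L, p), n %/% p), collapse = "")) {
      return(p)
    }
  }
  n
}

# lexicographically smallest rotation of a repeat unit (canonical phase)
canonical_unit <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(unit, i, n), substr(unit, 1L, i - 1L))
  }, character(1))
  sort(rots)[1]
}

#' Find simple sequence repeats (microsatellites)
#'
#' Scans the linearized sequence for maximal tandem repeats of unit sizes 1-6
#' passing the reporting thresholds. Loci whose unit is itself periodic
#' (e.g. ATAT as two units of AT) are reported at the smallest unit length
#' only; the unit is given in canonical phase (lexicographically smallest
#' rotation of the unit as read from the locus start). The reported `length`
#' is the full maximal tract including any trailing partial unit; `n_units`
#' counts complete units.
#'
#' @param sequence A DNA string (a plastome or any sequence).
#' @param thresholds Threshold list as returned by [ssr_thresholds()].
#' @return Tibble with columns `start`, `end`, `unit`, `unit_length`,
#'   `n_units`, `length` (1-based inclusive), sorted by `start`.
#' @examples
#' find_ssrs("GGAAAAAACC")   # one mono-SSR, unit A, length 6
#' find_ssrs("GATATATATG")   # one di-SSR, unit AT, 4 units
#' find_ssrs("GAAAAAC")      # empty: 5 x A is below threshold
#' @export
find_ssrs <- function(sequence, thresholds = ssr_thresholds()) {
  sequence <- toupper(sequence)
  s <- seq_chars(sequence)
  n <- length(s)
  out <- list()
  for (u in 1:6) {
    if (n < 2L * u) next
    min_len <- if (u == 1L) {
      thresholds$mono_min_length
    } else {
      u * thresholds$min_units[[as.character(u)]]
    }
    eq <- s[seq_len(n - u)] == s[seq_len(n - u) + u] &
      s[seq_len(n - u)] %in% DNA_BASES
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + u) >= min_len)
    for (h in hit) {
      st <- starts[h]
      tract_len <- r$lengths[h] + u
      unit <- substr(sequence, st, st + u - 1L)
      if (smallest_period(unit) < u) next  # reported at the smaller unit size
      n_units <- tract_len %/% u
      if (u > 1L && n_units < thresholds$min_units[[as.character(u)]]) next
      out[[length(out) + 1L]] <- tibble(
        start = st, end = st + tract_len - 1L,
        unit = canonical_unit(unit), unit_length = u,
        n_units = n_units, length = tract_len
      )
    }
  }
  if (!length(out)) {
    return(tibble(
      start = integer(), end = integer(), unit = character(),
      unit_length = integer(), n_units = integer(), length = integer()
    ))
  }
  list_rbind(out) |> arrange(.data$start, .data$unit_length)
}

#' SSR polymorphism across genomes through an alignment
#'
#' Groups homologous SSR loci found in several genomes via the columns of a
#' whole-genome alignment and flags positions where the number of repeat
#' units differs between genomes. Mononucleotide loci are reported but marked
#' separately (`mono = TRUE`): their length variation commonly reflects
#' within-individual heteroplasmy and they are excluded from the
#' recommended-marker set.
#'
#' @param loci Tibble of SSR loci across genomes with a `genome` column plus
#'   the [find_ssrs()] columns; coordinates are ungapped positions in each
#'   genome's own sequence.
#' @param alignment Named character vector (gapped rows), names matching
#'   `loci$genome`.
#' @return Tibble with one row per homologous SSR position: `position` (id),
#'   `col_start`, `col_end` (alignment columns), `unit_length`, `unit`,
#'   `counts` (list column of per-genome unit counts, `NA` where the locus is
#'   absent), `variable`, `mono`, `recommended`.
#' @export
ssr_polymorphism <- function(loci, alignment) {
  stopifnot(all(loci$genome %in% names(alignment)))
  maps <- lapply(alignment, aln_column_map)
  loci <- loci |>
    mutate(
      col_start = map2_int_(loci$genome, loci$start, maps),
      col_end = map2_int_(loci$genome, loci$end, maps)
    )
  # cluster loci of the same unit size whose column ranges overlap
  loci <- arrange(loci, .data$unit_length, .data$col_start)
  cluster <- integer(nrow(loci))
  cur <- 0L; cur_end <- -1L; cur_u <- -1L
  for (i in seq_len(nrow(loci))) {
    if (loci$unit_length[i] != cur_u || loci$col_start[i] > cur_end) {
      cur <- cur + 1L
      cur_u <- loci$unit_length[i]
      cur_end <- loci$col_end[i]
    } else {
      cur_end <- max(cur_end, loci$col_end[i])
    }
    cluster[i] <- cur
  }
  loci$position <- cluster
  genomes <- names(alignment)
  loci |>
    group_by(.data$position) |>
    summarise(
      col_start = min(.data$col_start), col_end = max(.data$col_end),
      unit_length = first(.data$unit_length), unit = first(.data$unit),
      counts = list(setNames(
        .data$n_units[match(genomes, .data$genome)], genomes
      )),
      .groups = "drop"
    ) |>
    mutate(
      variable = map_lgl(.data$counts, function(x) {
        n_distinct(x) > 1L  # NA (absent) vs present also counts as variable
      }),
      mono = .data$unit_length == 1L,
      recommended = .data$variable & !.data$mono
    )
}

map2_int_ <- function(genome, pos, maps) {
  vapply(seq_along(genome), function(i) maps[[genome[i]]][pos[i]], integer(1))
}
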