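# Independent brute-force oracles and shared fixtures.

# --- small, fast simulation fixture ----------------------------------------

small_sim_config <- function(seed = 1) {
  sim_config(
    seed = seed, plastome_length = 12000L, ir_length = 1500L,
    ssc_length = 2000L, n_genes = 6L, n_trna = 2L,
    gene_codon_range = c(60L, 120L), depth = 150, mito_length = 8000L,
    mtpt_spec = tibble::tibble(length = 500L, divergence = 0.02)
  )
}

.study_cache <- new.env(parent = emptyenv())
small_study <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- simulate_study(small_sim_config(seed))
  }
  .study_cache[[key]]
}

# --- SSR oracle: per-position greedy maximal-tandem scanner -----------------

brute_ssrs <- function(sequence, thresholds = ssr_thresholds()) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  rot_min <- function(u) {
    k <- nchar(u)
    min(vapply(seq_len(k), function(i) {
      paste0(substr(u, i, k), substr(u, 1, i - 1))
    }, character(1)))
  }
  is_periodic <- function(u) {
    k <- nchar(u)
    for (p in seq_len(k - 1)) {
      if (k %% p == 0 &&
          u == strrep(substr(u, 1, p), k / p)) return(TRUE)
    }
    FALSE
  }
  res <- list()
  for (u in 1:6) {
    for (i in seq_len(max(0, n - 2 * u + 1))) {
      unit <- paste(s[i:(i + u - 1)], collapse = "")
      if (grepl("[^ACGT]", unit) || (u > 1 && is_periodic(unit))) next
      # left maximality of the equality run
      if (i > 1 && s[i - 1] == s[i - 1 + u] && s[i - 1] %in% c("A","C","G","T")) next
      t <- u
      while (i + t <= n && s[i + t] == s[i + t - u] &&
             s[i + t] %in% c("A","C","G","T")) {
        t <- t + 1
      }
      if (t < 2 * u) next  # no complete second unit
      n_units <- t %/% u
      ok <- if (u == 1) t >= thresholds$mono_min_length else
        n_units >= thresholds$min_units[[as.character(u)]]
      if (!ok) next
      res[[length(res) + 1]] <- data.frame(
        start = i, end = i + t - 1, unit = rot_min(unit),
        unit_length = u, n_units = n_units, length = t,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), unit_length = integer(),
                      n_units = integer(), length = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$unit_length), , drop = FALSE]
}

# random sequence with runs (biased composition provokes more repeats)
biased_dna <- function(n, prob = c(0.35, 0.15, 0.15, 0.35)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# --- pileup oracle: naive per-read, per-base scan ---------------------------

brute_pileup <- function(reads, reference, min_bq = 20) {
  counts <- list()
  bump <- function(key, field, by = 1L) {
    if (is.null(counts[[key]])) {
      counts[[key]] <<- c(depth = 0L, A = 0L, C = 0L, G = 0L, T = 0L)
    }
    counts[[key]][field] <<- counts[[key]][field] + by
  }
  for (r in seq_len(nrow(reads))) {
    ops <- regmatches(reads$cigar[r],
                      gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[r]))[[1]]
    ref_pos <- reads$pos[r]
    read_pos <- 1L
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]", "", op))
      kind <- sub("[0-9]+", "", op)
      if (kind %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          key <- paste0(reads$strand[r], ref_pos)
          bump(key, "depth")
          q <- utf8ToInt(substr(reads$qual[r], read_pos, read_pos)) - 33L
          if (q >= min_bq) {
            b <- substr(reads$seq[r], read_pos, read_pos)
            if (b %in% c("A", "C", "G", "T")) bump(key, b)
          }
          ref_pos <- ref_pos + 1L
          read_pos <- read_pos + 1L
        }
      } else if (kind %in% c("D", "N")) {
        ref_pos <- ref_pos + len
      } else if (kind %in% c("I", "S")) {
        read_pos <- read_pos + len
      }
    }
  }
  keys <- names(counts)
  data.frame(
    strand = substr(keys, 1, 1),
    pos = as.integer(substring(keys, 2)),
    depth = vapply(counts, `[[`, integer(1), "depth"),
    A = vapply(counts, `[[`, integer(1), "A"),
    C = vapply(counts, `[[`, integer(1), "C"),
    G = vapply(counts, `[[`, integer(1), "G"),
    T = vapply(counts, `[[`, integer(1), "T"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# --- NG86 oracle: recursive exhaustive pathway enumeration ------------------

ng86_oracle <- function(s1, s2) {
  code <- Biostrings::GENETIC_CODE
  aa <- function(cdn) unname(code[cdn])
  stops <- names(code)[code == "*"]
  site_frac <- function(cdn) {
    syn <- 0
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cdn, p, p))) {
        m <- cdn
        substr(m, p, p) <- b
        if (!(m %in% stops) && aa(m) == aa(cdn)) syn <- syn + 1 / 3
      }
    }
    syn
  }
  paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(list(sd = 0, nd = 0, ok = TRUE)))
    out <- list()
    walk <- function(cur, remaining, sd, nd, ok) {
      if (!length(remaining)) {
        out[[length(out) + 1]] <<- list(sd = sd, nd = nd, ok = ok)
        return(invisible())
      }
      for (p in remaining) {
        nxt <- cur
        substr(nxt, p, p) <- substr(to, p, p)
        step_ok <- ok && !(nxt %in% stops && !(to %in% stops))
        step_syn <- aa(cur) == aa(nxt)
        walk(nxt, setdiff(remaining, p),
             sd + as.integer(step_syn), nd + as.integer(!step_syn), step_ok)
      }
    }
    walk(from, pos, 0, 0, TRUE)
    out
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (ci in seq_len(nchar(s1) / 3)) {
    c1 <- substr(s1, 3 * ci - 2, 3 * ci)
    c2 <- substr(s2, 3 * ci - 2, 3 * ci)
    if (grepl("[^ACGT]", paste0(c1, c2))) next
    sf <- (site_frac(c1) + site_frac(c2)) / 2
    S <- S + sf
    N <- N + 3 - sf
    pl <- paths(c1, c2)
    valid <- Filter(function(p) p$ok, pl)
    if (!length(valid)) valid <- pl
    Sd <- Sd + mean(vapply(valid, `[[`, numeric(1), "sd"))
    Nd <- Nd + mean(vapply(valid, `[[`, numeric(1), "nd"))
  }
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ks = jc(ps), ka = jc(pn))
}

# --- simple-indel-coding oracle: column-pattern formulation -----------------

sic_oracle <- function(alignment) {
  rows <- strsplit(unname(alignment), "")
  n <- length(rows[[1]])
  gap <- lapply(rows, function(r) r == "-")
  blocks <- unique(do.call(rbind, lapply(gap, function(g) {
    r <- rle(g)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1
    cbind(s[r$values], e[r$values])
  })))
  if (is.null(blocks) || !nrow(blocks)) {
    return(matrix(character(), nrow = length(alignment), ncol = 0,
                  dimnames = list(names(alignment), NULL)))
  }
  blocks <- blocks[order(blocks[, 1], blocks[, 2]), , drop = FALSE]
  m <- matrix("0", length(alignment), nrow(blocks),
              dimnames = list(names(alignment), NULL))
  for (t in seq_along(gap)) {
    g <- gap[[t]]
    for (b in seq_len(nrow(blocks))) {
      s <- blocks[b, 1]; e <- blocks[b, 2]
      covered <- all(g[s:e])
      left_open <- s > 1 && g[s - 1]
      right_open <- e < n && g[e + 1]
      m[t, b] <- if (covered && !left_open && !right_open) "1"
        else if (covered) "?" else "0"
    }
  }
  m
}

# --- toy read constructors --------------------------------------------------

toy_read <- function(qname, flag, pos, cigar, seq,
                     qual = strrep("I", nchar(seq)), strand = "+",
                     pnext = 1L, tlen = 0L) {
  tibble::tibble(
    qname = qname, flag = as.integer(flag), rname = "ref",
    pos = as.integer(pos), mapq = 60L, cigar = cigar, rnext = "=",
    pnext = as.integer(pnext), tlen = as.integer(tlen),
    seq = seq, qual = qual, strand = strand
  )
}

# a proper pair: read 1 reverse at `pos1`, read 2 forward at `pos2`
toy_pair <- function(qname, pos_fwd, pos_rev, len = 10,
                     ref = strrep("A", 200)) {
  seq_f <- substr(ref, pos_fwd, pos_fwd + len - 1)
  seq_r <- substr(ref, pos_rev, pos_rev + len - 1)
  dplyr::bind_rows(
    toy_read(qname, 1 + 2 + 16 + 64, pos_rev, paste0(len, "M"), seq_r,
             pnext = pos_fwd, tlen = -(pos_rev + len - pos_fwd)),
    toy_read(qname, 1 + 2 + 32 + 128, pos_fwd, paste0(len, "M"), seq_f,
             pnext = pos_rev, tlen = pos_rev + len - pos_fwd)
  ) |> dplyr::select(-"strand")
}
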