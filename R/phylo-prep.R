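# Preparation of phylogenetic inputs from whole-plastome alignments:
# inverted-repeat removal, homopolymer masking, codon-aware CDS
# concatenation with partition export, and simple indel coding.

#' Remove the IRa block from an alignment
#'
#' Drops all columns overlapping the IRa interval of a reference row,
#' including insertion columns (reference gaps) internal to the interval.
#'
#' @param alignment Named character vector of gapped rows.
#' @param ira_start,ira_end IRa interval in ungapped reference coordinates
#'   (1-based inclusive).
#' @param reference Name of the reference row (default: first row).
#' @return List with `alignment` (columns removed), `removed` (the column
#'   range dropped) and `column_map` (old column index of each kept column).
#' @export
remove_ira <- function(alignment, ira_start, ira_end,
                       reference = names(alignment)[1]) {
  if (is.null(ira_start) || is.null(ira_end) ||
      is.na(ira_start) || is.na(ira_end)) {
    abort("IRa boundaries are required to remove the repeat")
  }
  map <- aln_column_map(alignment[[reference]])
  col0 <- map[ira_start]
  col1 <- map[ira_end]
  keep <- setdiff(seq_len(nchar(alignment[[1]])), col0:col1)
  out <- vapply(alignment, function(row) {
    paste(seq_chars(row)[keep], collapse = "")
  }, character(1))
  list(alignment = out, removed = c(col0, col1), column_map = keep)
}

#' Mask homopolymer columns in an alignment
#'
#' Columns belonging to a mononucleotide run longer than `max_run`
#' (measured on the ungapped sequence of any row) are masked, restricted to
#' regions outside annotated CDS. When rows disagree on run length the union
#' of implicated columns is masked.
#'
#' @param alignment Named character vector of gapped rows.
#' @param cds Optional tibble of CDS intervals (`start`, `end`) in ungapped
#'   reference coordinates; masking is suppressed inside them.
#' @param max_run Maximum unmasked run length (default 5; runs *longer* than
#'   this are masked).
#' @param reference Reference row for interpreting `cds` coordinates.
#' @return List of class `plast_masked_alignment`: `alignment` (input),
#'   `mask` (tibble `column`, `reason`), and `masked_alignment` (rows with
#'   masked columns removed).
#' @export
mask_homopolymers <- function(alignment, cds = NULL, max_run = 5,
                              reference = names(alignment)[1]) {
  ncol_aln <- nchar(alignment[[1]])
  masked <- logical(ncol_aln)
  for (row in alignment) {
    ch <- seq_chars(row)
    cols <- which(ch != "-")
    bases <- ch[cols]
    r <- rle(bases)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$lengths > max_run & r$values %in% DNA_BASES)
    for (h in hit) {
      masked[cols[starts[h]:ends[h]]] <- TRUE
    }
  }
  if (!is.null(cds) && nrow(cds)) {
    map <- aln_column_map(alignment[[reference]])
    cds_cols <- unlist(lapply(seq_len(nrow(cds)), function(i) {
      map[cds$start[i]:cds$end[i]]
    }))
    masked[cds_cols] <- FALSE
  }
  keep <- which(!masked)
  out <- list(
    alignment = alignment,
    mask = tibble(column = which(masked), reason = "homopolymer"),
    masked_alignment = vapply(alignment, function(row) {
      paste(seq_chars(row)[keep], collapse = "")
    }, character(1))
  )
  class(out) <- "plast_masked_alignment"
  out
}

#' Simple indel coding of alignment gaps
#'
#' Codes each distinct gap block (a maximal run of gaps with identical start
#' and end columns across taxa) as one binary character. A taxon scores 1 if
#' it has exactly that block, `?` if one of its gaps strictly contains the
#' block's span (the character is inapplicable), and 0 otherwise (it has
#' nucleotides across the span).
#'
#' @param alignment Named character vector of gapped rows.
#' @return List of class `plast_indel_matrix`: `matrix` (character matrix,
#'   taxa x characters, entries "0"/"1"/"?") and `blocks` (tibble
#'   `character`, `col_start`, `col_end`).
#' @examples
#' simple_indel_coding(c(t1 = "A--T", t2 = "ACGT", t3 = "ACGT"))
#' @export
simple_indel_coding <- function(alignment) {
  taxa <- names(alignment)
  gap_runs <- lapply(alignment, function(row) {
    g <- seq_chars(row) == "-"
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(r$values)
    tibble(start = starts[i], end = ends[i])
  })
  blocks <- bind_rows(gap_runs) |>
    distinct() |>
    arrange(.data$start, .data$end)
  if (!nrow(blocks)) {
    out <- list(
      matrix = matrix(character(), nrow = length(taxa), ncol = 0,
                      dimnames = list(taxa, NULL)),
      blocks = tibble(character = integer(), col_start = integer(),
                      col_end = integer())
    )
    class(out) <- "plast_indel_matrix"
    return(out)
  }
  m <- matrix("0", nrow = length(taxa), ncol = nrow(blocks),
              dimnames = list(taxa, NULL))
  for (t in seq_along(taxa)) {
    runs <- gap_runs[[t]]
    for (b in seq_len(nrow(blocks))) {
      bs <- blocks$start[b]; be <- blocks$end[b]
      exact <- any(runs$start == bs & runs$end == be)
      contains <- any(runs$start <= bs & runs$end >= be &
                        (runs$start < bs | runs$end > be))
      m[t, b] <- if (exact) "1" else if (contains) "?" else "0"
    }
  }
  out <- list(
    matrix = m,
    blocks = tibble(character = seq_len(nrow(blocks)),
                    col_start = blocks$start, col_end = blocks$end)
  )
  class(out) <- "plast_indel_matrix"
  out
}

#' Concatenate CDS genes into a codon-aware supermatrix
#'
#' Spliced coding sequences are extracted per genome from the feature
#' tables (one copy per gene; minus-strand genes reverse-complemented) and
#' concatenated in alphabetical gene order. A gene missing from a genome is
#' filled with `?` over that gene's length. Genes whose extracted lengths
#' differ across genomes raise an error naming the gene (the function
#' expects length-matched, alignable CDS, e.g. from closely related
#' haplotypes or per-gene alignments).
#'
#' @param genomes Named character vector of genome sequences.
#' @param annotations Named list of feature tibbles (one per genome, same
#'   names as `genomes`).
#' @return List of class `plast_supermatrix`: `matrix` (named character
#'   vector of concatenated rows) and `partitions` (tibble `gene`, `start`,
#'   `end`).
#' @export
concatenate_cds <- function(genomes, annotations) {
  stopifnot(identical(sort(names(genomes)), sort(names(annotations))))
  gene_names <- sort(unique(unlist(lapply(annotations, function(a) {
    unique(a$gene[a$type == "CDS"])
  }))))
  per_gene <- lapply(gene_names, function(g) {
    vapply(names(genomes), function(id) {
      feats <- annotations[[id]]
      ex <- feats[feats$gene == g & feats$type == "CDS", , drop = FALSE]
      if (!nrow(ex)) return(NA_character_)
      extract_cds(genomes[[id]], ex)
    }, character(1))
  })
  names(per_gene) <- gene_names
  rows <- setNames(rep("", length(genomes)), names(genomes))
  parts <- list()
  offset <- 0L
  missing_log <- list()
  for (g in gene_names) {
    seqs <- per_gene[[g]]
    lens <- unique(nchar(seqs[!is.na(seqs)]))
    if (length(lens) != 1) {
      abort(sprintf("gene %s: CDS lengths differ across genomes (%s)",
                    g, paste(lens, collapse = ", ")))
    }
    filled <- ifelse(is.na(seqs), strrep("?", lens), seqs)
    if (any(is.na(seqs))) {
      missing_log[[g]] <- names(seqs)[is.na(seqs)]
    }
    rows <- paste0(rows, filled)
    parts[[g]] <- tibble(gene = g, start = offset + 1L, end = offset + lens)
    offset <- offset + lens
  }
  out <- list(
    matrix = setNames(rows, names(genomes)),
    partitions = list_rbind(parts),
    missing = missing_log
  )
  class(out) <- "plast_supermatrix"
  out
}

# spliced CDS of one gene (exon rows sorted by rank; minus strand revcomp'd)
extract_cds <- function(sequence, exons) {
  exons <- exons[order(exons$exon), , drop = FALSE]
  s <- paste(substring(sequence, exons$start, exons$end), collapse = "")
  if (exons$strand[1] == "-") revcomp(s) else s
}

#' Write a supermatrix as relaxed PHYLIP
#' @param sm A `plast_supermatrix` or named character vector of rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  rows <- if (inherits(sm, "plast_supermatrix")) sm$matrix else sm
  lines <- c(
    sprintf(" %d %d", length(rows), nchar(rows[[1]])),
    sprintf("%s  %s", names(rows), unname(rows))
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write RAxML-style partition text
#' @param sm A `plast_supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(sm, path) {
  readr::write_lines(
    sprintf("DNA, %s = %d-%d", sm$partitions$gene,
            sm$partitions$start, sm$partitions$end),
    path
  )
  invisible(path)
}

#' Write a NEXUS file with a DNA partition and a binary indel partition
#'
#' Binary characters use symbols 0/1 with `?` for inapplicable.
#'
#' @param rows Named character vector of aligned DNA rows.
#' @param indels A `plast_indel_matrix` (or NULL for DNA only).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(rows, indels = NULL, path) {
  taxa <- names(rows)
  nchar_dna <- nchar(rows[[1]])
  nchar_bin <- if (!is.null(indels)) ncol(indels$matrix) else 0L
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa),
            nchar_dna + nchar_bin),
    sprintf(paste0("  FORMAT DATATYPE=MIXED(DNA:1-%d,RESTRICTION:%d-%d) ",
                   "MISSING=? GAP=- SYMBOLS=\"01\";"),
            nchar_dna, nchar_dna + 1L, nchar_dna + nchar_bin),
    "  MATRIX"
  )
  if (nchar_bin == 0) {
    lines[4] <- "  FORMAT DATATYPE=DNA MISSING=? GAP=-;"
  }
  for (t in taxa) {
    bin <- if (nchar_bin > 0) paste(indels$matrix[t, ], collapse = "") else ""
    lines <- c(lines, sprintf("  %s  %s%s", t, rows[[t]], bin))
  }
  lines <- c(lines, "  ;", "END;")
  readr::write_lines(lines, path)
  invisible(path)
}
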