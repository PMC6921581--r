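# File input/output. FASTA goes through Biostrings; GFF3 through rtracklayer's
# reader when available (falling back to a plain tabular read is not needed in
# this package: writing is column-ordered text, reading uses rtracklayer).
# All emitted tables are 1-based, inclusive coordinates; writers say so in a
# header comment.

#' Read a FASTA file into a named character vector
#'
#' Ambiguity codes other than N are rejected with an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  check_alphabet(seqs, where = path)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write a feature table as GFF3
#'
#' Feature tables are tibbles with one row per exon: columns `gene`, `type`
#' (CDS/tRNA/rRNA), `strand`, `start`, `end`, `exon` (exon rank, 1-based).
#' Coordinates are 1-based inclusive, as in GFF3.
#'
#' @param features Feature tibble.
#' @param path Output path.
#' @param seqid Sequence name to write in column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seqid = "plastome") {
  lines <- c(
    "##gff-version 3",
    "# coordinates: 1-based, inclusive",
    sprintf(
      "%s\tplastkit\t%s\t%d\t%d\t.\t%s\t%s\tID=%s.%d;gene=%s",
      seqid, features$type, features$start, features$end,
      features$strand,
      ifelse(features$type == "CDS", as.character(cds_phase(features)), "."),
      features$gene, features$exon, features$gene
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

# phase of each CDS exon row (cumulative length of preceding exons mod 3)
cds_phase <- function(features) {
  features |>
    group_by(.data$gene) |>
    arrange(.data$exon, .by_group = TRUE) |>
    mutate(.phase = (3L - cumsum(dplyr::lag(.data$end - .data$start + 1L,
                                            default = 0L)) %% 3L) %% 3L) |>
    ungroup() |>
    pull(".phase")
}

#' Read a GFF3 file into a feature table
#'
#' @param path Path to a GFF3 file written by [write_gff3()] or compatible.
#' @return Feature tibble (`gene`, `type`, `strand`, `start`, `end`, `exon`).
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::readGFF(path)
  tb <- as_tibble(as.data.frame(g))
  exon <- if ("ID" %in% names(tb)) {
    as.integer(sub("^.*\\.", "", tb$ID))
  } else {
    1L
  }
  tibble(
    gene = as.character(tb$gene),
    type = as.character(tb$type),
    strand = as.character(tb$strand),
    start = as.integer(tb$start),
    end = as.integer(tb$end),
    exon = exon
  ) |>
    arrange(.data$start, .data$exon)
}

#' Write read alignments as SAM text
#'
#' @param reads Read tibble with the 11 mandatory SAM columns
#'   (`qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`,
#'   `tlen`, `seq`, `qual`).
#' @param path Output path.
#' @param ref_name,ref_length Reference name and length for the `@SQ` line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, ref_name, ref_length) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_length))
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
    reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
    reads$cigar, reads$rnext, reads$pnext, reads$tlen, reads$seq, reads$qual
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read SAM text into a read tibble
#'
#' Only the 11 mandatory columns are retained; optional tags are dropped.
#' Positions are 1-based, as in SAM.
#'
#' @param path Path to a SAM file.
#' @return Read tibble.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = integer(), tlen = integer(),
      seq = character(), qual = character()
    ))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i) vapply(f, `[[`, character(1), i)
  tibble(
    qname = col(1), flag = as.integer(col(2)), rname = col(3),
    pos = as.integer(col(4)), mapq = as.integer(col(5)), cigar = col(6),
    rnext = col(7), pnext = as.integer(col(8)), tlen = as.integer(col(9)),
    seq = toupper(col(10)), qual = col(11)
  )
}

# write a tibble as TSV with a coordinate-convention comment header
write_tsv_commented <- function(x, path, comment = "# coordinates: 1-based, inclusive") {
  readr::write_lines(comment, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
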