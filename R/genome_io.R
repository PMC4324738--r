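#' Construct a genome record
#'
#' A genome record is the package's canonical container for a single
#' nucleotide sequence: an identifier, the sequence over the `{A,C,G,T}`
#' alphabet (`U` is accepted on input and normalized to `T`; `N` is allowed
#' and flagged with a warning), a circularity flag, and the length in
#' nucleotides.  All coordinates used anywhere in the package are 1-based
#' inclusive positions on this sequence.
#'
#' @param id character identifier.
#' @param seq nucleotide string; case-insensitive, `U` normalized to `T`.
#' @param circular logical; mitochondrial genomes are circular but are
#'   treated as linear unless wrap-around extraction is explicitly requested.
#' @return An object of class `genome_record` with fields `id`, `seq`,
#'   `circular`, `length`.
#' @export
genome_record <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- normalize_seq(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("N", seq, fixed = TRUE))
    warning("sequence contains ambiguous residues (N)")
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 length = nchar(seq)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record %s: %d nt (%s)\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# uppercase, U -> T; reject anything outside A,C,G,T,N
normalize_seq <- function(seq) {
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside the A/C/G/T/U/N alphabet")
  s
}

#' Read a genome from a FASTA file
#'
#' Reads a single record (or a selected record of a multi-record file) and
#' returns a normalized [genome_record()].
#'
#' @param path path to a FASTA file.
#' @param id optional record identifier to select from a multi-record file;
#'   a multi-record file without `id` is rejected.
#' @param circular logical circularity flag to attach.
#' @return A [genome_record()].
#' @export
read_genome_fasta <- function(path, id = NULL, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file")
  nms <- sub("\\s.*$", "", names(set))
  if (is.null(id)) {
    if (length(set) > 1L)
      stop("multi-record FASTA; select a record with `id`")
    sel <- 1L
  } else {
    sel <- match(id, nms)
    if (is.na(sel)) stop("record not found in FASTA: ", id)
  }
  seq <- as.character(set[[sel]])
  if (nchar(gsub("[^A-Za-z]", "", seq)) == 0L) stop("empty sequence in FASTA")
  genome_record(nms[sel], seq, circular = circular)
}

#' Write a genome to FASTA
#'
#' @param genome a [genome_record()].
#' @param path output path.
#' @param rna emit `U` instead of `T` (RNA alphabet).
#' @param width line width.
#' @export
write_genome_fasta <- function(genome, path, rna = FALSE, width = 70L) {
  seq <- genome$seq
  if (rna) seq <- chartr("T", "U", seq)
  x <- Biostrings::BStringSet(seq)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string (A/C/G/T/U/N).
#' @return The reverse complement, on the T alphabet.
#' @export
revcomp <- function(seq) {
  s <- normalize_seq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract a subsequence by 1-based inclusive interval
#'
#' Strand `"-"` returns the reverse complement of the plus-strand slice.  On
#' a circular genome an interval with `end > length` wraps around the origin
#' when `wrap = TRUE`; wrap-around must be requested explicitly.
#'
#' @param genome a [genome_record()].
#' @param start,end 1-based inclusive positions; `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @param wrap allow wrap-around extraction on a circular genome.
#' @return Nucleotide string of length `end - start + 1`.
#' @export
extract_interval <- function(genome, start, end, strand = "+", wrap = FALSE) {
  stopifnot(inherits(genome, "genome_record"))
  if (start < 1L || end < start) stop("invalid interval: [", start, ",", end, "]")
  L <- genome$length
  if (end > L) {
    if (!(genome$circular && wrap))
      stop("interval out of range on linear genome: [", start, ",", end, "]")
    if (end - start + 1L > L) stop("wrap-around interval longer than genome")
    idx <- ((seq.int(start, end) - 1L) %% L) + 1L
    s <- paste(strsplit(genome$seq, "", fixed = TRUE)[[1L]][idx], collapse = "")
  } else {
    s <- substr(genome$seq, start, end)
  }
  if (strand == "-") s <- revcomp(s)
  s
}

#' Read a MITOMAP-style gene map
#'
#' Tab-separated columns `name`, `start`, `end`, `strand`, `description`
#' (header optional, detected).  Coordinates are 1-based inclusive; rows are
#' returned sorted by start.  Overlapping genes are permitted (neighboring
#' mitochondrial genes can share a boundary position).
#'
#' @param path TSV file path.
#' @return data.frame with columns name, start, end, strand, description.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty gene map: ", path)
    return(data.frame(name = character(), start = integer(), end = integer(),
                      strand = character(), description = character(),
                      stringsAsFactors = FALSE))
  }
  has_header <- grepl("^name\t", lines[1L], ignore.case = TRUE)
  if (has_header) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    name = vapply(parts, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    strand = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, ""),
    description = vapply(parts, function(p) if (length(p) >= 5L) p[5L] else "", ""),
    stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  if (length(bad))
    stop("invalid gene map row(s) at line ",
         paste(bad + has_header, collapse = ", "),
         " (need integer start <= end)")
  out[order(out$start, out$end), , drop = FALSE]
}

#' Read a disease-to-gene table
#'
#' Tab-separated columns `disease`, `genes`, where `genes` is a
#' comma-separated list of gene symbols.
#'
#' @param path TSV file path.
#' @return Named list mapping disease name to character vector of genes.
#' @export
read_disease_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^disease\t", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) trimws(strsplit(p[2L], ",", fixed = TRUE)[[1L]]))
  names(out) <- vapply(parts, `[`, "", 1L)
  out
}

# ---- standard-format interval export ---------------------------------------

intervals_to_granges <- function(df, seqname, score = NULL, name = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  gr
}

#' Export intervals as BED6
#'
#' Converts from the package's 1-based inclusive convention to BED's 0-based
#' half-open convention (handled by the `rtracklayer` exporter).
#'
#' @param df data.frame with `start`, `end` and optionally `strand` columns.
#' @param seqname chromosome/sequence name for all intervals.
#' @param path output file.
#' @param name,score optional per-interval name and score vectors.
#' @export
export_bed <- function(df, seqname, path, name = NULL, score = NULL) {
  gr <- intervals_to_granges(df, seqname, score = score, name = name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export intervals as GFF3 (1-based inclusive)
#'
#' @inheritParams export_bed
#' @param type feature type column for the GFF3 `type` field.
#' @param source source label.
#' @export
export_gff3 <- function(df, seqname, path, type = "region",
                        source = "mitomir", name = NULL, score = NULL) {
  gr <- intervals_to_granges(df, seqname, score = score, name = name)
  gr$type <- type
  gr$source <- source
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
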