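#' Parameters for miRNA target scanning
#'
#' The two-phase procedure first scores 5'-weighted complementarity between
#' the miRNA and the target strand (phase 1), then evaluates the
#' intermolecular duplex free energy of every high-scoring site (phase 2).
#' A site is emitted only when `S >= min_S` and `dG <= dG_cutoff`.
#'
#' @param gap_open,gap_extend gap penalties, subtracted as
#'   `open + extend * length` (the printed defaults, open 2 < extend 8, are
#'   unusual for affine schemes and are flagged with a message when used;
#'   both orderings are supported).
#' @param min_S minimum complementarity score.
#' @param dG_cutoff maximum (most positive) duplex free energy, kcal/mol.
#' @param w seed scaling factor applied to per-column scores at miRNA
#'   positions `seed_range`; position 1 is never weighted.
#' @param seed_range miRNA positions (5'-based) forming the seed.
#' @param match_score,wobble_score,mismatch_score per-column base scores for
#'   Watson-Crick, G:U wobble and mismatched columns.
#' @param forbid_seed_GU disallow G:U pairs in the seed during the duplex
#'   energy phase.
#' @param allow_gaps set `FALSE` for ungapped phase-1 scanning.
#' @return List of class `target_scan_params`.
#' @export
target_scan_params <- function(gap_open = 2.0, gap_extend = 8.0,
                               min_S = 150.0, dG_cutoff = -25.0, w = 3.0,
                               seed_range = c(2L, 8L),
                               match_score = 5.0, wobble_score = 1.0,
                               mismatch_score = -3.0,
                               forbid_seed_GU = FALSE, allow_gaps = TRUE) {
  stopifnot(min_S > 0, w >= 1, length(seed_range) == 2L)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 min_S = min_S, dG_cutoff = dG_cutoff, w = w,
                 seed_range = as.integer(seed_range),
                 match_score = match_score, wobble_score = wobble_score,
                 mismatch_score = mismatch_score,
                 forbid_seed_GU = isTRUE(forbid_seed_GU),
                 allow_gaps = isTRUE(allow_gaps)),
            class = "target_scan_params")
}

#' Phase 1: 5'-weighted complementarity scan
#'
#' Local alignment of the miRNA (5'->3') against one or both strands of the
#' target, antiparallel, with Watson-Crick / wobble / mismatch column scores
#' multiplied by `w` at seed positions.  Returns all local optima with
#' `S >= min_S` (overlapping lower-scoring alignments suppressed).
#'
#' @param mirna mature miRNA sequence, 5'->3'.
#' @param target a [genome_record()] or nucleotide string.
#' @param params a [target_scan_params()].
#' @param strands strands to scan (`"+"`, `"-"`).
#' @return data.frame with target `start`, `end`, `strand`, covered miRNA
#'   positions, score `S`, and alignment strings.
#' @export
complementarity_scan <- function(mirna, target, params = target_scan_params(),
                                 strands = c("+", "-")) {
  mirna <- normalize_seq(mirna)
  if (nchar(mirna) < params$seed_range[2L])
    stop("miRNA shorter than the seed range")
  if (params$gap_extend > params$gap_open && params$allow_gaps)
    message("note: gap_extend > gap_open (penalties used as configured)")
  seq <- if (inherits(target, "genome_record")) target$seq else normalize_seq(target)
  L <- nchar(seq)
  out <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq else revcomp(seq)
    df <- .complementarity_scan_cpp(mirna, s,
                                    params$match_score, params$wobble_score,
                                    params$mismatch_score,
                                    params$gap_open, params$gap_extend,
                                    params$w, params$seed_range[1L],
                                    params$seed_range[2L],
                                    params$min_S, params$allow_gaps)
    if (nrow(df) == 0L) next
    if (strand == "-") {
      start <- L - df$end + 1L
      df$end <- L - df$start + 1L
      df$start <- start
      df <- df[order(df$start, df$end), , drop = FALSE]
    }
    df$strand <- strand
    out[[strand]] <- df
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      mirna_from = integer(), mirna_to = integer(),
                      S = numeric(), aln_mirna = character(),
                      aln_pairs = character(), aln_target = character(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Phase 2: intermolecular duplex free energy
#'
#' Minimum free energy of the miRNA hybridized to a candidate site, over
#' intermolecular base pairs only (no intramolecular structure), with
#' stacks and bulge/internal-loop penalties shared with the folding model.
#' The duplex of a sequence with its perfect complement attains the model
#' minimum over all site alignments; a sequence with no complementarity
#' (e.g. poly-A against poly-A) has `dG = 0`.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param site_seq binding-site sequence 5'->3' on the bound strand.
#' @param model a [fold_model()].
#' @param forbid_seed_GU disallow G:U at miRNA seed positions.
#' @param seed_range seed positions used when `forbid_seed_GU`.
#' @return List with `dG` (kcal/mol, <= 0), `pairing` (per-miRNA-position
#'   string: `|` Watson-Crick, `:` wobble, `.` unpaired), and the pair lists.
#' @export
hybrid_dG <- function(mirna, site_seq, model = fold_model(),
                      forbid_seed_GU = FALSE, seed_range = c(2L, 8L)) {
  mirna <- normalize_seq(mirna)
  site_seq <- normalize_seq(site_seq)
  if (!nzchar(mirna) || !nzchar(site_seq)) stop("empty sequence")
  n <- max(nchar(mirna), nchar(site_seq))
  bl <- extend_loop_table(model$bulge, n, model$loop_extrapolation)
  il <- extend_loop_table(model$internal, n, model$loop_extrapolation)
  .hybrid_dg_cpp(mirna, site_seq, model$stack, bl, il, model$max_loop,
                 isTRUE(forbid_seed_GU), seed_range[1L], seed_range[2L])
}

#' Predict miRNA target sites on a genome
#'
#' Runs [complementarity_scan()] and filters each hit by [hybrid_dG()];
#' emits only sites passing both `S >= min_S` and `dG <= dG_cutoff`.
#' Ordering is deterministic: target position, then miRNA id.
#'
#' @param mirnas named character vector of mature miRNA sequences, or a path
#'   to a FASTA file of them.
#' @param target a [genome_record()].
#' @param params a [target_scan_params()].
#' @param model a [fold_model()] for the duplex phase.
#' @param tool label recorded in the `tool` column.
#' @param strands strands to scan.
#' @return data.frame of target sites: `mirna_id`, `start`, `end`, `strand`,
#'   `S`, `dG`, alignment and pairing strings, `tool`.
#' @export
predict_targets <- function(mirnas, target, params = target_scan_params(),
                            model = fold_model(), tool = "miranda-like",
                            strands = c("+", "-")) {
  if (is.character(mirnas) && length(mirnas) == 1L && file.exists(mirnas))
    mirnas <- read_mirna_fasta(mirnas)
  empty <- data.frame(mirna_id = character(), start = integer(),
                      end = integer(), strand = character(), S = numeric(),
                      dG = numeric(), aln_mirna = character(),
                      aln_pairs = character(), aln_target = character(),
                      pairing = character(), tool = character(),
                      stringsAsFactors = FALSE)
  if (!length(mirnas)) return(empty)
  ids <- names(mirnas)
  if (is.null(ids)) ids <- paste0("mir", seq_along(mirnas))
  rows <- list()
  for (k in seq_along(mirnas)) {
    hits <- complementarity_scan(mirnas[[k]], target, params)
    if (nrow(hits) == 0L) next
    for (h in seq_len(nrow(hits))) {
      site_seq <- extract_interval(target, hits$start[h], hits$end[h],
                                   strand = hits$strand[h])
      hy <- hybrid_dG(mirnas[[k]], site_seq, model,
                      forbid_seed_GU = params$forbid_seed_GU,
                      seed_range = params$seed_range)
      if (hy$dG > params$dG_cutoff) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = ids[k], start = hits$start[h], end = hits$end[h],
        strand = hits$strand[h], S = hits$S[h], dG = hy$dG,
        aln_mirna = hits$aln_mirna[h], aln_pairs = hits$aln_pairs[h],
        aln_target = hits$aln_target[h], pairing = hy$pairing,
        tool = tool, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$end, res$mirna_id), , drop = FALSE]
  stopifnot(all(res$S >= params$min_S), all(res$dG <= params$dG_cutoff))
  rownames(res) <- NULL
  res
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of T-normalized sequences.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- vapply(seq_along(set), function(k) normalize_seq(as.character(set[[k]])), "")
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write target sites as TSV
#'
#' @param sites data.frame from [predict_targets()] or compatible.
#' @param path output file.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-tool target-site TSV
#'
#' Accepts externally produced site lists (columns `tool`, `mirna_id`,
#' `start`, `end`, optionally `score`/`S` and `dG`).
#'
#' @param path TSV file with a header line.
#' @param tool optional tool label overriding the file's `tool` column.
#' @return data.frame of sites.
#' @export
read_sites_tsv <- function(path, tool = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(tool)) df$tool <- tool
  if (!"tool" %in% names(df)) stop("site list needs a `tool` column or label")
  need <- c("mirna_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("site list needs columns: ", paste(need, collapse = ", "))
  df
}
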