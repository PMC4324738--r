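#' Fold a sequence into its minimum-free-energy secondary structure
#'
#' Exact dynamic program over pseudoknot-free structures under a
#' nearest-neighbor [fold_model()]: stacks, hairpin loops (minimum loop
#' length 3), bulges, internal loops (two-sided size capped at
#' `model$max_loop`), and affine multiloops.  G:U wobble pairs are allowed.
#' The open chain is always admissible at energy 0, so the MFE is never
#' positive; it is 0 exactly when the best structure is the open chain.
#' Deterministic for a fixed model (fixed-order tie-breaks).
#'
#' @param seq nucleotide string (A/C/G/T/U).
#' @param model a [fold_model()].
#' @return List of class `fold_result`: `seq`, `structure` (dot-bracket),
#'   `mfe` (kcal/mol), `n_paired`, `n_terminal_loops`.
#' @export
fold_mfe <- function(seq, model = fold_model()) {
  seq <- normalize_seq(seq)
  if (grepl("N", seq, fixed = TRUE))
    stop("cannot fold sequence containing N")
  n <- nchar(seq)
  if (n < model$min_loop + 2L) stop("sequence shorter than min_loop + 2")
  hp <- extend_loop_table(model$hairpin, n, model$loop_extrapolation)
  bl <- extend_loop_table(model$bulge, n, model$loop_extrapolation)
  il <- extend_loop_table(model$internal, n, model$loop_extrapolation)
  res <- .fold_mfe_cpp(seq, model$stack, hp, bl, il,
                       model$ml_close, model$ml_branch, model$ml_unpaired,
                       model$min_loop, model$max_loop)
  structure(list(seq = seq, structure = res$structure, mfe = res$mfe,
                 n_paired = res$n_paired,
                 n_terminal_loops = count_terminal_loops(res$structure)),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, sprintf(" (%.2f)\n", x$mfe), sep = "")
  invisible(x)
}

# terminal (hairpin) loops = '(' followed only by dots until ')'
count_terminal_loops <- function(structure) {
  length(gregexpr("\\(\\.*\\)", structure)[[1L]]) -
    (gregexpr("\\(\\.*\\)", structure)[[1L]][1L] == -1L)
}

#' Vienna-style text for folded sequences
#'
#' @param ids,seqs,folds parallel vectors/list of identifiers, sequences and
#'   [fold_mfe()] results.
#' @param path output file.
#' @export
write_vienna <- function(ids, seqs, folds, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(ids)) {
    writeLines(c(paste0(">", ids[k]), seqs[k],
                 sprintf("%s (%.2f)", folds[[k]]$structure, folds[[k]]$mfe)), con)
  }
  invisible(path)
}

#' Single-hairpin test for a fold
#'
#' TRUE iff the structure has exactly one terminal loop, at least
#' `min_stem_pairs` paired bases, and a terminal loop length within
#' `loop_range`.
#'
#' @param fold a `fold_result`.
#' @param min_stem_pairs minimum paired-base count (both strands counted).
#' @param loop_range allowed terminal loop length, nt.
#' @export
is_single_hairpin <- function(fold, min_stem_pairs = 16L,
                              loop_range = c(3L, 30L)) {
  if (fold$n_terminal_loops != 1L) return(FALSE)
  if (fold$n_paired < min_stem_pairs) return(FALSE)
  m <- regmatches(fold$structure, regexpr("\\(\\.*\\)", fold$structure))[[1L]]
  loop_len <- nchar(m) - 2L
  loop_len >= loop_range[1L] && loop_len <= loop_range[2L]
}

#' Triplet structure-sequence features
#'
#' The classic 32-dimensional feature vector for pre-miRNA classification:
#' for every interior position, the central nucleotide (A/C/G/U) is combined
#' with the paired/unpaired pattern of the three local positions
#' (previous, central, next; `1` = paired), giving 4 x 8 buckets; counts are
#' normalized to sum to 1.
#'
#' @param seq nucleotide string.
#' @param structure dot-bracket (or any string where `.` means unpaired) of
#'   the same length.
#' @return Named numeric vector of length 32, e.g. `"A.011"`; sums to 1 for
#'   any sequence of length >= 3.
#' @export
triplet_features <- function(seq, structure) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (nchar(structure) != n) stop("sequence/structure length mismatch")
  if (n < 3L) stop("sequence shorter than 3 nt")
  bases <- strsplit(chartr("T", "U", seq), "", fixed = TRUE)[[1L]]
  paired <- as.integer(strsplit(structure, "", fixed = TRUE)[[1L]] != ".")
  nts <- c("A", "C", "G", "U")
  pats <- do.call(paste0, expand.grid(0:1, 0:1, 0:1)[, 3:1])
  keys <- paste0(rep(nts, each = 8L), ".", rep(pats, 4L))
  v <- stats::setNames(numeric(32L), keys)
  for (i in 2:(n - 1L)) {
    if (!bases[i] %in% nts) next
    key <- paste0(bases[i], ".", paired[i - 1L], paired[i], paired[i + 1L])
    v[key] <- v[key] + 1
  }
  if (sum(v) > 0) v <- v / sum(v)
  v
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erikson shuffle: generates a random sequence with exactly the
#' same dinucleotide (and therefore mononucleotide) composition, first and
#' last residue as the input, by drawing a uniform random Eulerian walk on
#' the dinucleotide multigraph.
#'
#' @param seq nucleotide string, length >= 4.
#' @return A shuffled string.
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(s)
  if (n < 4L) stop("sequence too short to shuffle (< 4 nt)")
  last <- s[n]
  verts <- unique(s)
  edges <- split(s[-1L], factor(s[-n], levels = verts))   # out-edges per vertex
  if (length(verts) == 1L) return(seq)                     # homopolymer

  # draw a random "last edge" per vertex (except the terminal one) until the
  # chosen edges form an arborescence into the terminal vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last && !length(edges[[v]])) return(NA_character_)
      e <- edges[[v]]
      if (!length(e)) return(NA_character_)
      e[sample.int(length(e), 1L)]
    }, "")
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }

  # permute remaining out-edges uniformly; append the reserved last edge
  ordered <- lapply(verts, function(v) {
    e <- edges[[v]]
    reserved <- v != last && !is.na(last_edge[[v]])
    if (reserved) e <- e[-match(last_edge[[v]], e)]
    e <- if (length(e)) e[sample.int(length(e))] else character(0)
    if (reserved) e <- c(e, last_edge[[v]])
    e
  })
  names(ordered) <- verts

  # walk
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n); out[1L] <- s[1L]; cur <- s[1L]
  for (k in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Randomization P-value for folding stability
#'
#' Folds `n` dinucleotide-preserving shuffles of the sequence and reports
#' `P = (1 + #\{MFE_shuffle <= MFE_observed\}) / (n + 1)`.  Reproducible for
#' a fixed seed; the caller's RNG state is left untouched.
#'
#' @param seq nucleotide string, length >= 4.
#' @param model a [fold_model()].
#' @param n number of shuffles.
#' @param seed integer RNG seed.
#' @return List with `p`, `mfe`, `n`, `seed`.
#' @export
shuffle_pvalue <- function(seq, model = fold_model(), n = 1000L, seed = 1L) {
  stopifnot(n >= 1L)
  if (nchar(seq) < 4L) stop("sequence too short to shuffle (< 4 nt)")
  mfe_obs <- fold_mfe(seq, model)$mfe
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n)) {
    sh <- dinucleotide_shuffle(seq)
    if (fold_mfe(sh, model)$mfe <= mfe_obs + 1e-9) hits <- hits + 1L
  }
  list(p = (1 + hits) / (n + 1), mfe = mfe_obs, n = n, seed = seed)
}

#' Rule thresholds for the real-vs-pseudo hairpin filter
#'
#' A transparent rule filter standing where trained classifiers would sit in
#' a web-server pipeline: a candidate is called `real` iff its fold is a
#' single hairpin, its MFE is at most `mfe_max`, and its shuffle P-value is
#' at most `p_max`.  The 32 triplet features are computed and exported
#' alongside so that users can plug in their own classifier.
#'
#' @param mfe_max MFE acceptance ceiling, kcal/mol.
#' @param p_max randomization P-value ceiling.
#' @param min_stem_pairs,loop_range forwarded to [is_single_hairpin()].
#' @export
candidate_rules <- function(mfe_max = -18, p_max = 0.05,
                            min_stem_pairs = 16L, loop_range = c(3L, 30L)) {
  list(mfe_max = mfe_max, p_max = p_max,
       min_stem_pairs = min_stem_pairs, loop_range = loop_range)
}

#' Classify a hairpin window as real or pseudo pre-miRNA
#'
#' @param features list with at least `shuffle_p` (e.g. from
#'   [shuffle_pvalue()]) or a numeric `shuffle_p` value.
#' @param fold the window's `fold_result`.
#' @param rules a [candidate_rules()] list.
#' @return `"real"` or `"pseudo"`.
#' @export
classify_candidate <- function(features, fold, rules = candidate_rules()) {
  p <- if (is.list(features)) features$shuffle_p else features
  ok <- is_single_hairpin(fold, rules$min_stem_pairs, rules$loop_range) &&
    fold$mfe <= rules$mfe_max && p <= rules$p_max
  if (ok) "real" else "pseudo"
}

#' Pick the mature-arm window from a folded precursor
#'
#' Slides a window of the requested length along each stem arm (the runs of
#' positions 5' and 3' of the single terminal loop) and returns the window
#' maximizing the number of paired positions; ties break to the 5'-most
#' window.  Returns `NULL` (candidate rejected) when no arm can host a
#' window of the requested length or the fold has no terminal loop.
#'
#' @param fold a `fold_result` for the precursor window.
#' @param length mature length in nt (19-22 typical; default 21).
#' @return List with `start`, `end` (1-based within the precursor), `seq`,
#'   `arm` (`"5p"` or `"3p"`), `n_paired`; or `NULL`.
#' @export
pick_mature <- function(fold, length = 21L) {
  st <- fold$structure
  m <- regexpr("\\(\\.*\\)", st)
  if (m == -1L) return(NULL)
  loop_start <- as.integer(m) + 1L
  loop_end <- as.integer(m) + attr(m, "match.length") - 2L
  n <- nchar(st)
  paired <- as.integer(strsplit(st, "", fixed = TRUE)[[1L]] != ".")
  arms <- list(`5p` = c(1L, loop_start - 1L), `3p` = c(loop_end + 1L, n))
  best <- NULL
  for (arm in names(arms)) {
    a <- arms[[arm]]
    if (a[2L] - a[1L] + 1L < length) next
    for (s in a[1L]:(a[2L] - length + 1L)) {
      np <- sum(paired[s:(s + length - 1L)])
      if (is.null(best) || np > best$n_paired) {
        best <- list(start = s, end = s + length - 1L,
                     seq = substr(fold$seq, s, s + length - 1L),
                     arm = arm, n_paired = np)
      }
    }
  }
  best
}
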