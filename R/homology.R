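#' Build a nonoverlapping k-mer seed index of a genome
#'
#' BLAT-style index: the words are the k-mers starting on the grid
#' `1, k+1, 2k+1, ...` of the target genome, indexed for both strands.
#' Words occurring more often than `repeat_cap` (per strand) are masked as
#' repeat-heavy and dropped from the index.
#'
#' @param genome a [genome_record()].
#' @param k word size (default 11).
#' @param repeat_cap maximum occurrences of a grid word before masking.
#' @return List of class `seed_index` with per-strand word tables.
#' @export
build_seed_index <- function(genome, k = 11L, repeat_cap = 8L) {
  stopifnot(inherits(genome, "genome_record"), genome$length >= k)
  grid_words <- function(seq) {
    L <- nchar(seq)
    starts <- seq.int(1L, by = k, length.out = L %/% k)
    words <- substring(seq, starts, starts + k - 1L)
    keep <- !grepl("N", words, fixed = TRUE)
    tab <- split(starts[keep], words[keep])
    tab[lengths(tab) <= repeat_cap]
  }
  structure(list(id = genome$id, k = as.integer(k),
                 repeat_cap = as.integer(repeat_cap),
                 length = genome$length,
                 seq_plus = genome$seq,
                 seq_minus = revcomp(genome$seq),
                 plus = grid_words(genome$seq),
                 minus = grid_words(revcomp(genome$seq))),
            class = "seed_index")
}

# ungapped extension of a seeded diagonal; returns the maximal-scoring
# segment (match +1 / mismatch -1) around the seed
extend_ungapped <- function(q, t, qpos, tpos, k) {
  qs <- strsplit(q, "", fixed = TRUE)[[1L]]
  ts <- strsplit(t, "", fixed = TRUE)[[1L]]
  off <- tpos - qpos
  lo <- max(1L, 1L - off)               # query positions on this diagonal
  hi <- min(length(qs), length(ts) - off)
  sc <- ifelse(qs[lo:hi] == ts[(lo + off):(hi + off)], 1L, -1L)
  # maximal-scoring contiguous segment (Kadane with positions)
  best <- 0L; best_i <- 0L; best_j <- -1L
  cur <- 0L; cur_i <- 1L
  for (i in seq_along(sc)) {
    cur <- cur + sc[i]
    if (cur < 0L) { cur <- 0L; cur_i <- i + 1L }
    else if (cur > best) { best <- cur; best_i <- cur_i; best_j <- i }
  }
  if (best_j < best_i) return(NULL)
  q1 <- lo + best_i - 1L; q2 <- lo + best_j - 1L
  matches <- sum(sc[best_i:best_j] == 1L)
  list(q_start = q1, q_end = q2, t_start = q1 + off, t_end = q2 + off,
       matches = matches, length = q2 - q1 + 1L)
}

#' Seed-and-extend homology search for a short query
#'
#' Looks up every k-mer of the query in the grid index, extends each seed
#' ungapped in both directions maximizing match - mismatch, and reports the
#' maximal segments passing the identity and length filters, on both
#' strands.  Coordinates are on the forward strand of the indexed genome.
#'
#' @param query nucleotide string, length >= `min_len`.
#' @param index a [build_seed_index()] object.
#' @param min_len minimum reported alignment length (default 20).
#' @param min_identity minimum fraction of matching columns (default 0.95).
#' @return data.frame of hits: `start`, `end`, `strand`, `matches`,
#'   `mismatches`, `length`, `identity`.
#' @export
homology_search <- function(query, index, min_len = 20L, min_identity = 0.95) {
  query <- normalize_seq(query)
  if (nchar(query) < min_len) stop("query shorter than min_len")
  k <- index$k
  hits <- list()
  for (strand in c("+", "-")) {
    words <- if (strand == "+") index$plus else index$minus
    tseq <- if (strand == "+") index$seq_plus else index$seq_minus
    if (nchar(query) < k) next
    qstarts <- seq_len(nchar(query) - k + 1L)
    qwords <- substring(query, qstarts, qstarts + k - 1L)
    seen <- character(0)
    for (qi in seq_along(qwords)) {
      tpos_all <- words[[qwords[qi]]]
      if (is.null(tpos_all)) next
      for (tpos in tpos_all) {
        diag_key <- paste0(strand, ":", tpos - qstarts[qi])
        if (diag_key %in% seen) next
        seen <- c(seen, diag_key)
        ext <- extend_ungapped(query, tseq, qstarts[qi], tpos, k)
        if (is.null(ext)) next
        if (ext$length < min_len) next
        identity <- ext$matches / ext$length
        if (identity < min_identity) next
        # map minus-strand coordinates back to the forward strand
        if (strand == "+") {
          st <- ext$t_start; en <- ext$t_end
        } else {
          st <- index$length - ext$t_end + 1L
          en <- index$length - ext$t_start + 1L
        }
        hits[[length(hits) + 1L]] <- data.frame(
          start = st, end = en, strand = strand,
          matches = ext$matches, mismatches = ext$length - ext$matches,
          length = ext$length, identity = identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      matches = integer(), mismatches = integer(),
                      length = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  out <- out[order(-out$identity, -out$length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-hit homology table across genomes
#'
#' For each (query, genome) cell reports the best hit (highest identity,
#' then longest, then smallest start) or absence, plus the total number of
#' homologs found.
#'
#' @param queries named character vector of query sequences.
#' @param genomes list of [genome_record()]s.
#' @param k,repeat_cap,min_len,min_identity forwarded to the index/search.
#' @return List with `table` (data.frame: query, genome, start, end, strand,
#'   identity, length; NA where absent) and `n_hits` (count of non-absent
#'   cells).
#' @export
homology_table <- function(queries, genomes, k = 11L, repeat_cap = 8L,
                           min_len = 20L, min_identity = 0.95) {
  if (!length(genomes))
    return(list(table = data.frame(), n_hits = 0L))
  qids <- names(queries)
  if (is.null(qids)) qids <- paste0("q", seq_along(queries))
  rows <- list()
  n_hits <- 0L
  for (g in genomes) {
    idx <- build_seed_index(g, k = k, repeat_cap = repeat_cap)
    for (qi in seq_along(queries)) {
      h <- homology_search(queries[[qi]], idx, min_len, min_identity)
      if (nrow(h)) {
        n_hits <- n_hits + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          query = qids[qi], genome = g$id,
          start = h$start[1L], end = h$end[1L], strand = h$strand[1L],
          identity = h$identity[1L], length = h$length[1L],
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          query = qids[qi], genome = g$id,
          start = NA_integer_, end = NA_integer_, strand = NA_character_,
          identity = NA_real_, length = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, rows), n_hits = n_hits)
}
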