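# Independent oracles used across the suite.  Each one recomputes a quantity
# by brute force or closed form, through a different algorithmic route than
# the implementation under test.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

can_pair <- function(a, b)
  paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")

# --- inverted repeats: split the sequence at every point and take the best
# local alignment of the prefix against the reverse complement of the suffix
# (complementary columns become identities), linear gap penalty.
oracle_ir_best <- function(seq, match = 3, mismatch = -4, gap = 12) {
  n <- nchar(seq)
  letters4 <- c("A", "C", "G", "T")
  mat <- matrix(mismatch, 4, 4, dimnames = list(letters4, letters4))
  diag(mat) <- match
  best <- 0
  for (cpt in seq_len(n - 1)) {
    a <- substr(seq, 1, cpt)
    b <- revcomp(substr(seq, cpt + 1, n))
    sc <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = gap,
                                        scoreOnly = TRUE)
    best <- max(best, sc)
  }
  best
}

# --- folding: enumerate every pseudoknot-free structure with min_loop >= 3
enum_structures <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1]]
  n <- length(s)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste0(i, ",", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- paste0(".", rec(i + 1, j))
    ks <- if (i + min_loop + 1 <= j) seq.int(i + min_loop + 1, j) else integer(0)
    for (k in ks) {
      if (!can_pair(s[i], s[k])) next
      inner <- rec(i + 1, k - 1)
      rest <- rec(k + 1, j)
      out <- c(out, as.vector(outer(inner, rest,
                                    function(x, y) paste0("(", x, ")", y))))
    }
    memo[[key]] <- out
    out
  }
  if (n == 0) return(character(0))
  rec(1, n)
}

oracle_fold_min <- function(seq, model = fold_model()) {
  structs <- enum_structures(seq, model$min_loop)
  min(vapply(structs, function(st) structure_energy(seq, st, model), 0))
}

# --- duplex: enumerate all monotone non-crossing intermolecular pairings
enum_duplex_min <- function(mirna, site, model = fold_model(),
                            forbid_seed_gu = FALSE, seed = c(2, 8)) {
  a <- strsplit(chartr("U", "T", toupper(mirna)), "", fixed = TRUE)[[1]]
  b <- strsplit(chartr("U", "T", toupper(site)), "", fixed = TRUE)[[1]]
  m <- length(a); s <- length(b)
  ptm <- c(AT = 1, TA = 2, CG = 3, GC = 4, GT = 5, TG = 6)
  ok_pair <- function(i, j) {
    key <- paste0(a[i], b[j])
    if (!key %in% names(ptm)) return(FALSE)
    if (forbid_seed_gu && key %in% c("GT", "TG") &&
        i >= seed[1] && i <= seed[2]) return(FALSE)
    TRUE
  }
  lt <- function(tab, sz)
    mitomir:::extend_loop_table(tab, max(sz, 1), model$loop_extrapolation)[sz]
  link <- function(pi, pj, ni, nj) {
    ga <- ni - pi - 1; gb <- pj - nj - 1
    if (ga == 0 && gb == 0)
      model$stack[ptm[[paste0(a[pi], b[pj])]], ptm[[paste0(a[ni], b[nj])]]]
    else if (ga + gb > model$max_loop) Inf
    else if (ga == 0 || gb == 0) lt(model$bulge, ga + gb)
    else lt(model$internal, ga + gb)
  }
  best <- 0
  # walk every monotone chain of pairs, accumulating energy incrementally
  rec <- function(pi, pj, e) {
    if (e < best) best <<- e
    if (pi + 1 > m || pj - 1 < 1) return()
    for (i in (pi + 1):m) for (j in seq_len(pj - 1))
      if (ok_pair(i, j)) {
        de <- link(pi, pj, i, j)
        if (is.finite(de)) rec(i, j, e + de)
      }
  }
  for (i in seq_len(m)) for (j in seq_len(s))
    if (ok_pair(i, j)) rec(i, j, 0)
  best
}

# --- ungapped complementarity scan: per-diagonal maximal weighted segment
oracle_scan_best <- function(mirna, strand_seq, params) {
  q <- strsplit(mirna, "", fixed = TRUE)[[1]]
  tt <- strsplit(strand_seq, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(tt)
  colscore <- function(p, tb) {
    key <- paste0(q[p], tb)
    s <- if (key %in% c("AT", "TA", "CG", "GC")) params$match_score
    else if (key %in% c("GT", "TG")) params$wobble_score
    else params$mismatch_score
    if (p >= params$seed_range[1] && p <= params$seed_range[2]) s * params$w else s
  }
  best <- 0
  for (off in (1 - m):(n - 1)) {
    cur <- 0
    for (k in seq_len(m)) {
      tp <- off + k
      if (tp < 1 || tp > n) next
      cur <- max(0, cur + colscore(m + 1 - k, tt[tp]))
      best <- max(best, cur)
    }
  }
  best
}

# --- dinucleotide composition fingerprint
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# a genome with planted strong hairpins and perfect target sites, plus truth
make_planted_fixture <- function(seed, genome_len = 3000, n_hairpins = 5,
                                 n_targets = 3, arm_len = 30, loop_len = 10) {
  g <- make_genome(genome_len, gc_frac = 0.3, seed = seed)
  span <- arm_len * 2 + loop_len
  slot <- genome_len %/% (n_hairpins + n_targets + 1)
  hp_truth <- list()
  for (k in seq_len(n_hairpins)) {
    p <- plant_hairpin(g, arm_len, loop_len, 0, pos = k * slot,
                       seed = seed + k, gc_frac = 0.6)
    g <- p$genome
    hp_truth[[k]] <- p$truth
  }
  mirs <- character(n_targets)
  tg_truth <- list()
  set.seed(seed + 1000)
  for (k in seq_len(n_targets)) {
    mirs[k] <- rand_seq(21, gc = 0.5)
    p <- plant_target(g, mirs[k], "perfect", pos = (n_hairpins + k) * slot,
                      seed = seed + 100 + k)
    g <- p$genome
    tg_truth[[k]] <- p$truth
  }
  if (n_targets > 0) names(mirs) <- paste0("mir", seq_len(n_targets))
  list(genome = g, hairpins = hp_truth, mirnas = mirs, targets = tg_truth)
}
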