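#' Nearest-neighbor RNA folding energy model
#'
#' Bundles the thermodynamic parameters used by [fold_mfe()], [hybrid_dG()]
#' and [anneal_dG()]: a 6x6 stack table over the canonical pair types
#' (A:U, U:A, C:G, G:C, G:U, U:G), tabulated hairpin / bulge / internal loop
#' penalties with logarithmic extrapolation beyond the tabulated sizes, an
#' affine multiloop term, the minimum hairpin loop length, and the standard
#' cap on two-sided loop size.  Watson-Crick stack free energies follow the
#' Turner-style nearest-neighbor set for RNA at 37 degrees C; stacks
#' involving G:U wobble pairs are derived from the Watson-Crick values with a
#' fixed destabilization per wobble pair.  The model is plain data: any entry
#' can be overridden, and a model can be round-tripped through YAML with
#' [write_fold_model()] / [read_fold_model()].
#'
#' @param wobble_penalty destabilization in kcal/mol added per G:U pair in a
#'   stack (relative to the A:U-mapped Watson-Crick value).
#' @param min_loop minimum hairpin loop length in nt.
#' @param max_loop maximum total unpaired size of a bulge/internal loop.
#' @param ml_close,ml_branch,ml_unpaired affine multiloop parameters in
#'   kcal/mol: closing penalty, per-branch penalty (the closing pair counts
#'   as a branch), per-unpaired-base penalty.
#' @return A list of class `fold_model`.
#' @export
fold_model <- function(wobble_penalty = 0.7, min_loop = 3L, max_loop = 30L,
                       ml_close = 3.4, ml_branch = 0.4, ml_unpaired = 0.0) {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  # Watson-Crick stack dG37 (kcal/mol), indexed [outer, inner]:
  # outer pair (i,j), inner pair (i+1, j-1)
  wc <- matrix(NA_real_, 4, 4, dimnames = list(pairs[1:4], pairs[1:4]))
  wc["AU", "AU"] <- -0.93; wc["AU", "UA"] <- -1.10
  wc["AU", "CG"] <- -2.24; wc["AU", "GC"] <- -2.08
  wc["UA", "AU"] <- -1.33; wc["UA", "UA"] <- -0.93
  wc["UA", "CG"] <- -2.35; wc["UA", "GC"] <- -2.11
  wc["CG", "AU"] <- -2.11; wc["CG", "UA"] <- -2.08
  wc["CG", "CG"] <- -3.26; wc["CG", "GC"] <- -2.36
  wc["GC", "AU"] <- -2.35; wc["GC", "UA"] <- -2.24
  wc["GC", "CG"] <- -3.42; wc["GC", "GC"] <- -3.26

  # extend to wobble pairs: map GU->AU, UG->UA and destabilize per wobble
  map_wc <- c(AU = "AU", UA = "UA", CG = "CG", GC = "GC", GU = "AU", UG = "UA")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  for (p1 in pairs) for (p2 in pairs) {
    nw <- (p1 %in% c("GU", "UG")) + (p2 %in% c("GU", "UG"))
    stack[p1, p2] <- min(wc[map_wc[[p1]], map_wc[[p2]]] + wobble_penalty * nw,
                         -0.1)
  }

  # loop initiation penalties (kcal/mol), tabulated to size 30;
  # larger loops are extrapolated as E(30) + 1.75 * R * T * log(L / 30)
  lcoef <- 1.75 * 0.0019872 * 310.15
  hp <- rep(Inf, 30)
  hp[3:9] <- c(5.4, 5.6, 5.7, 5.8, 5.9, 6.0, 6.1)
  hp[10:30] <- hp[9] + lcoef * log((10:30) / 9)
  bl <- numeric(30)
  bl[1:6] <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
  bl[7:30] <- bl[6] + lcoef * log((7:30) / 6)
  il <- rep(Inf, 30)
  il[2:6] <- c(1.7, 1.8, 1.9, 2.0, 2.1)
  il[7:30] <- il[6] + lcoef * log((7:30) / 6)

  structure(list(pairs = pairs, stack = stack,
                 hairpin = hp, bulge = bl, internal = il,
                 loop_extrapolation = lcoef,
                 min_loop = as.integer(min_loop),
                 max_loop = as.integer(max_loop),
                 ml_close = ml_close, ml_branch = ml_branch,
                 ml_unpaired = ml_unpaired),
            class = "fold_model")
}

# extend a tabulated loop-penalty vector to length n by log extrapolation
extend_loop_table <- function(tab, n, lcoef) {
  m <- length(tab)
  if (n <= m) return(tab[seq_len(n)])
  c(tab, tab[m] + lcoef * log(((m + 1):n) / m))
}

#' Serialize a fold model to YAML
#' @param model a [fold_model()].
#' @param path output file.
#' @export
write_fold_model <- function(model, path) {
  x <- unclass(model)
  x$stack <- as.list(as.data.frame(x$stack))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a fold model back from YAML
#' @param path YAML file written by [write_fold_model()].
#' @return A `fold_model` object.
#' @export
read_fold_model <- function(path) {
  x <- yaml::read_yaml(path)
  stack <- do.call(cbind, lapply(x$stack, unlist))
  rownames(stack) <- x$pairs
  x$stack <- stack
  x$hairpin <- unlist(x$hairpin)
  x$bulge <- unlist(x$bulge)
  x$internal <- unlist(x$internal)
  class(x) <- "fold_model"
  x
}

# pair type of two bases on the T-normalized alphabet; 0 if not pairable
pair_type <- function(a, b) {
  key <- paste0(chartr("T", "U", a), chartr("T", "U", b))
  m <- c(AU = 1L, UA = 2L, CG = 3L, GC = 4L, GU = 5L, UG = 6L)
  v <- m[key]
  ifelse(is.na(v), 0L, v)
}

#' Free energy of a given secondary structure
#'
#' Scores an explicit dot-bracket structure under a [fold_model()] by loop
#' decomposition: stacks, hairpin loops, bulges, internal loops, multiloops
#' (affine), zero-cost exterior loop.  This is the reference evaluator for
#' the energy model; [fold_mfe()] minimizes exactly this quantity.
#'
#' @param seq nucleotide string.
#' @param structure dot-bracket string of the same length.
#' @param model a [fold_model()].
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(seq, structure, model = fold_model()) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (nchar(structure) != n) stop("sequence/structure length mismatch")
  ch <- strsplit(structure, "", fixed = TRUE)[[1L]]
  bases <- strsplit(chartr("T", "U", seq), "", fixed = TRUE)[[1L]]
  # pair table
  stack_ <- integer(0); pt <- integer(n)
  for (k in seq_len(n)) {
    if (ch[k] == "(") stack_ <- c(stack_, k)
    else if (ch[k] == ")") {
      if (!length(stack_)) stop("unbalanced structure")
      i <- stack_[length(stack_)]; stack_ <- stack_[-length(stack_)]
      pt[i] <- k; pt[k] <- i
    }
  }
  if (length(stack_)) stop("unbalanced structure")

  hp <- function(sz) extend_loop_table(model$hairpin, max(sz, 1), model$loop_extrapolation)[sz]
  bl <- function(sz) extend_loop_table(model$bulge, max(sz, 1), model$loop_extrapolation)[sz]
  il <- function(sz) extend_loop_table(model$internal, max(sz, 1), model$loop_extrapolation)[sz]

  ptype_at <- function(i, j) {
    t <- pair_type(bases[i], bases[j])
    if (t == 0L) stop("non-canonical pair at (", i, ",", j, ")")
    t
  }

  e <- 0.0
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j <= i) next                     # each pair handled at its opening
    # children: pairs immediately nested inside (i, j)
    kids <- list(); k <- i + 1L; unpaired <- 0L
    while (k < j) {
      if (pt[k] > k) { kids[[length(kids) + 1L]] <- c(k, pt[k]); k <- pt[k] + 1L }
      else { unpaired <- unpaired + 1L; k <- k + 1L }
    }
    if (length(kids) == 0L) {
      e <- e + hp(j - i - 1L)
    } else if (length(kids) == 1L) {
      k <- kids[[1L]][1L]; l <- kids[[1L]][2L]
      a <- k - i - 1L; b <- j - l - 1L
      if (a == 0L && b == 0L)
        e <- e + model$stack[ptype_at(i, j), ptype_at(k, l)]
      else if (a == 0L || b == 0L)
        e <- e + bl(a + b)
      else
        e <- e + il(a + b)
    } else {
      e <- e + model$ml_close + model$ml_branch * (length(kids) + 1L) +
        model$ml_unpaired * unpaired
    }
  }
  e
}
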