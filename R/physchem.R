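#' Residue composition of an RNA sequence
#'
#' Counts A, U, C, G residues (T counted as U).
#'
#' @param seq nucleotide string.
#' @return Named integer vector `c(An, Un, Cn, Gn)` summing to the length.
#' @export
composition <- function(seq) {
  s <- chartr("T", "U", normalize_seq(seq))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  c(An = sum(ch == "A"), Un = sum(ch == "U"),
    Cn = sum(ch == "C"), Gn = sum(ch == "G"))
}

#' Molecular weight of an RNA molecule
#'
#' `Mw = An*329.21 + Un*306.17 + Cn*305.18 + Gn*329.21 + 159.0` g/mol, the
#' standard oligonucleotide-calculator formula; the constant 159.0 accounts
#' for the 5' triphosphate and is added once per molecule.
#'
#' @param seq nonempty nucleotide string (T treated as U).
#' @param kda return kilodaltons instead of g/mol.
#' @return Molecular weight (g/mol by default).
#' @export
molecular_weight <- function(seq, kda = FALSE) {
  if (!nzchar(seq)) stop("empty sequence")
  cmp <- composition(seq)
  mw <- cmp[["An"]] * 329.21 + cmp[["Un"]] * 306.17 +
    cmp[["Cn"]] * 305.18 + cmp[["Gn"]] * 329.21 + 159.0
  if (kda) mw / 1000 else mw
}

#' GC and AU content percentages
#'
#' @param seq nonempty nucleotide string.
#' @return Named numeric `c(gc_pct, au_pct)`; the two sum to exactly 100 for
#'   pure-ACGU input.
#' @export
gc_au_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  cmp <- composition(seq)
  len <- sum(cmp)
  gc <- 100 * (cmp[["Cn"]] + cmp[["Gn"]]) / len
  # complement form keeps gc + au == 100 exact in floating point
  c(gc_pct = gc, au_pct = 100 - gc)
}

# Xia-style RNA nearest-neighbor dH (kcal/mol) and dS (cal/mol/K) by
# top-strand dinucleotide step (duplex with the perfect complement)
.nn_dh_ds <- function() {
  steps <- c("AA", "AU", "UA", "CU", "CA", "GU", "GA", "CG", "GG", "GC")
  dh <- c(AA = -6.82, AU = -9.38, UA = -7.69, CU = -10.48, CA = -10.44,
          GU = -11.40, GA = -12.44, CG = -10.64, GG = -13.39, GC = -14.88)
  ds <- c(AA = -19.0, AU = -26.7, UA = -20.5, CU = -27.1, CA = -26.9,
          GU = -29.5, GA = -32.5, CG = -26.7, GG = -32.7, GC = -36.9)
  # remaining 6 steps by rotational symmetry: XY == rc(XY)
  rc2 <- function(d) chartr("AUCG", "UAGC",
                            paste(rev(strsplit(d, "")[[1L]]), collapse = ""))
  for (d in c("UU", "UC", "UG", "AC", "AG", "CC")) {
    dh[d] <- dh[[rc2(d)]]
    ds[d] <- ds[[rc2(d)]]
  }
  list(dh = dh, ds = ds, init_dh = 3.61, init_ds = -1.5)
}

#' Annealing free energy of a sequence with its perfect complement
#'
#' Nearest-neighbor `dG = dH - T * dS` over the duplex of the sequence with
#' its exact complement, using an RNA dH/dS step table plus a duplex
#' initiation term.  The stated standard conditions (strand concentration
#' 50 nM, 50 mM Na+, pH 7.0) are recorded in the result; no salt or
#' concentration correction is applied to the free energy itself.
#'
#' @param seq nonempty nucleotide string.
#' @param temperature temperature in K (default 298.15).
#' @return List with `dG` (kcal/mol), `dH`, `dS`, and `conditions`.
#' @export
anneal_dG <- function(seq, temperature = 298.15) {
  s <- chartr("T", "U", normalize_seq(seq))
  if (grepl("N", s, fixed = TRUE)) stop("ambiguous residues in sequence")
  nn <- .nn_dh_ds()
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  dh <- nn$init_dh; ds <- nn$init_ds
  if (length(ch) >= 2L) {
    for (k in seq_len(length(ch) - 1L)) {
      step <- paste0(ch[k], ch[k + 1L])
      dh <- dh + nn$dh[[step]]
      ds <- ds + nn$ds[[step]]
    }
  }
  list(dG = dh - temperature * ds / 1000,
       dH = dh, dS = ds,
       conditions = list(primer_nM = 50, na_mM = 50, pH = 7.0,
                         temperature_K = temperature,
                         R_cal_per_mol_K = 1.987))
}

#' Physicochemical property report
#'
#' Tabulates length, %GC, %AU, molecular weight (g/mol and kDa) and
#' annealing free energy for a set of sequences.
#'
#' @param seqs named character vector of sequences.
#' @param temperature temperature in K for [anneal_dG()].
#' @return data.frame, one row per sequence.
#' @export
physchem_report <- function(seqs, temperature = 298.15) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(k) {
    ga <- gc_au_content(seqs[[k]])
    mw <- molecular_weight(seqs[[k]])
    data.frame(id = ids[k], length = nchar(seqs[[k]]),
               gc_pct = ga[["gc_pct"]], au_pct = ga[["au_pct"]],
               mw_g_mol = mw, mw_kda = mw / 1000,
               dG_kcal_mol = anneal_dG(seqs[[k]], temperature)$dG,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
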