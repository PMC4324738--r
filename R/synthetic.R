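#' Generate a random genome at a requested GC fraction
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc_frac / 2 and
#' P(A) = P(T) = (1 - gc_frac) / 2.  Identical seed, identical genome; the
#' caller's RNG state is preserved.
#'
#' @param length genome length in nt (>= 1).
#' @param gc_frac GC fraction in `[0, 1]`.
#' @param circular circularity flag for the resulting record.
#' @param seed integer seed.
#' @param id record identifier.
#' @return A [genome_record()].
#' @export
make_genome <- function(length, gc_frac = 0.44, circular = FALSE,
                        seed = 1L, id = "synthetic") {
  stopifnot(length >= 1L, gc_frac >= 0, gc_frac <= 1)
  with_seed(seed, {
    bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                    prob = c((1 - gc_frac) / 2, (1 - gc_frac) / 2,
                             gc_frac / 2, gc_frac / 2))
    genome_record(id, paste(bases, collapse = ""), circular = circular)
  })
}

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# overwrite genome$seq at pos with the replacement string
splice_seq <- function(genome, pos, replacement) {
  L <- nchar(replacement)
  if (pos < 1L || pos + L - 1L > genome$length)
    stop("planted span exceeds genome")
  seq <- paste0(substr(genome$seq, 1L, pos - 1L), replacement,
                substr(genome$seq, pos + L, genome$length))
  genome_record(genome$id, seq, genome$circular)
}

#' Plant an inverted-repeat hairpin into a genome
#'
#' Writes `arm + loop + reverse-complement(arm)` at the given position, with
#' `n_mismatches` random substitutions in the right arm.  The returned truth
#' record carries the planted coordinates and the expected inverted-repeat
#' alignment score under a scoring scheme (`match * (arm_len - n_mismatches)
#' + mismatch * n_mismatches`).
#'
#' @param genome a [genome_record()].
#' @param arm_len,loop_len arm and loop lengths in nt.
#' @param n_mismatches substitutions placed in the right arm.
#' @param pos 1-based start of the hairpin span.
#' @param seed integer seed for arm sequence and mismatch placement.
#' @param gc_frac GC fraction of the random arm.
#' @param params [repeat_params()] used for the expected score.
#' @return List `genome` (modified record) and `truth` (list with `start`,
#'   `end`, `left_arm`, `right_arm`, `loop`, `expected_score`).
#' @export
plant_hairpin <- function(genome, arm_len, loop_len, n_mismatches = 0L,
                          pos, seed = 1L, gc_frac = 0.5,
                          params = repeat_params()) {
  stopifnot(arm_len >= 1L, loop_len >= 0L, n_mismatches <= max(arm_len - 2L, 0L))
  with_seed(seed, {
    arm <- paste(sample(c("A", "T", "G", "C"), arm_len, replace = TRUE,
                        prob = c((1 - gc_frac) / 2, (1 - gc_frac) / 2,
                                 gc_frac / 2, gc_frac / 2)), collapse = "")
    # poly-A loop cannot pair with itself, so the stem never grows inward
    loop <- strrep("A", max(loop_len, 0L))
    right <- strsplit(revcomp(arm), "", fixed = TRUE)[[1L]]
    if (n_mismatches > 0L) {
      # interior positions only: terminal mismatches would be trimmed by
      # local alignment and change the expected score
      at <- (2:(arm_len - 1L))[sample.int(arm_len - 2L, n_mismatches)]
      for (i in at) {
        right[i] <- sample(setdiff(c("A", "C", "G", "T"), right[i]), 1L)
      }
    }
    insert <- paste0(arm, loop, paste(right, collapse = ""))
    g2 <- splice_seq(genome, pos, insert)
    # non-complementary guard bands (A opposite C) so random flanking bases
    # cannot extend the planted stem outward
    ins <- 6L
    span_len <- nchar(insert)
    left_g <- max(1L, pos - ins)
    if (left_g < pos)
      g2 <- splice_seq(g2, left_g, strrep("A", pos - left_g))
    right_g <- min(g2$length, pos + span_len - 1L + ins)
    if (right_g > pos + span_len - 1L)
      g2 <- splice_seq(g2, pos + span_len,
                       strrep("C", right_g - (pos + span_len) + 1L))
    span <- arm_len * 2L + loop_len
    truth <- list(start = pos, end = pos + span - 1L,
                  left_arm = c(pos, pos + arm_len - 1L),
                  right_arm = c(pos + arm_len + loop_len, pos + span - 1L),
                  loop = loop_len, arm_len = arm_len,
                  n_mismatches = n_mismatches,
                  expected_score = params$match * (arm_len - n_mismatches) +
                    params$mismatch * n_mismatches)
    list(genome = g2, truth = truth)
  })
}

#' Plant a miRNA target site into a genome
#'
#' Inserts the reverse complement of the miRNA (profile `"perfect"`), a
#' variant with mismatches confined outside the seed (`"seed-only"`), or a
#' heavily mismatched variant (`"weak"`, 8 substitutions) at `pos` on the
#' plus strand.  The truth record states whether the site is expected to
#' pass default [target_scan_params()].
#'
#' @param genome a [genome_record()].
#' @param mirna mature miRNA sequence 5'->3'.
#' @param profile `"perfect"`, `"seed-only"` or `"weak"`.
#' @param pos 1-based start of the planted site.
#' @param seed integer seed for mismatch placement.
#' @return List `genome` and `truth` (`start`, `end`, `profile`,
#'   `expect_pass`).
#' @export
plant_target <- function(genome, mirna, profile = c("perfect", "seed-only", "weak"),
                         pos, seed = 1L) {
  profile <- match.arg(profile)
  mirna <- normalize_seq(mirna)
  m <- nchar(mirna)
  site <- revcomp(mirna)       # site read 5'->3' pairs the miRNA end-to-end
  with_seed(seed, {
    ch <- strsplit(site, "", fixed = TRUE)[[1L]]
    n_mm <- switch(profile, perfect = 0L, `seed-only` = 3L, weak = 8L)
    if (n_mm > 0L) {
      # site position s pairs miRNA position m - s + 1; seed = miRNA 2..8
      non_seed_site <- which(!(m - seq_len(m) + 1L) %in% 2:8)
      at <- if (profile == "seed-only")
        sample(non_seed_site, n_mm) else sample.int(m, n_mm)
      for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    g2 <- splice_seq(genome, pos, paste(ch, collapse = ""))
    truth <- list(start = pos, end = pos + m - 1L, strand = "+",
                  profile = profile,
                  # perfect sites pass default thresholds, weak ones fail;
                  # seed-only sites sit near the S threshold (NA = untested)
                  expect_pass = switch(profile, perfect = TRUE,
                                       weak = FALSE, `seed-only` = NA))
    list(genome = g2, truth = truth)
  })
}

#' Write a synthetic gene map
#'
#' @param genes data.frame with `name`, `start`, `end` and optionally
#'   `strand`, `description`.
#' @param path output TSV.
#' @export
write_gene_map <- function(genes, path) {
  if (!"strand" %in% names(genes)) genes$strand <- "H"
  if (!"description" %in% names(genes)) genes$description <- ""
  utils::write.table(genes[, c("name", "start", "end", "strand", "description")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a disease-to-gene table
#'
#' @param diseases named list mapping disease name to gene symbols.
#' @param path output TSV.
#' @export
write_disease_map <- function(diseases, path) {
  lines <- c("disease\tgenes",
             vapply(names(diseases), function(d)
               paste0(d, "\t", paste(diseases[[d]], collapse = ",")), ""))
  writeLines(lines, path)
  invisible(path)
}
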