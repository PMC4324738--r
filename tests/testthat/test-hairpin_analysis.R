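test_that("MFE folding handles trivial and textbook cases", {
  # no complementary pairs at all
  f <- fold_mfe(strrep("A", 20))
  expect_equal(f$structure, strrep(".", 20))
  expect_equal(f$mfe, 0)
  expect_equal(f$n_paired, 0L)

  # perfect mini stem-loop
  f <- fold_mfe(paste0(strrep("G", 5), "AAAA", strrep("C", 5)))
  expect_equal(f$structure, "(((((....)))))")
  expect_lt(f$mfe, 0)
  expect_equal(structure_energy(f$seq, f$structure), f$mfe)

  expect_error(fold_mfe("ACGNT"), "N")
})

test_that("the MFE is never positive and is 0 only for the open chain", {
  set.seed(41)
  for (k in 1:25) {
    f <- fold_mfe(rand_seq(sample(10:60, 1)))
    expect_lte(f$mfe, 0)
    if (f$n_paired > 0) expect_lte(f$mfe, -0.1 + 1e-12)
    if (f$mfe == 0) expect_equal(f$n_paired, 0L)
    # structure energy of the reported structure matches the reported MFE
    expect_equal(structure_energy(f$seq, f$structure), f$mfe, tolerance = 1e-9)
  }
})

test_that("DP optimum equals exhaustive structure enumeration on short sequences", {
  set.seed(43)
  model <- fold_model()
  for (k in 1:30) {
    s <- rand_seq(sample(8:16, 1), gc = 0.6)
    expect_equal(fold_mfe(s, model)$mfe, oracle_fold_min(s, model),
                 tolerance = 1e-9, info = s)
  }
})

test_that("single-hairpin detection counts terminal loops", {
  mk <- function(st, np) structure(list(structure = st, n_paired = np,
                                        n_terminal_loops =
                                          mitomir:::count_terminal_loops(st)),
                                   class = "fold_result")
  expect_true(is_single_hairpin(mk("(((((....)))))", 10L),
                                min_stem_pairs = 5L))
  expect_false(is_single_hairpin(mk("((..))..((..))", 8L),
                                 min_stem_pairs = 2L))
  expect_false(is_single_hairpin(mk("..........", 0L), min_stem_pairs = 0L))
  # loop length out of range
  expect_false(is_single_hairpin(mk("((((....))))", 8L), min_stem_pairs = 2L,
                                 loop_range = c(5, 10)))
})

test_that("triplet features bucket local structure patterns and sum to 1", {
  v <- triplet_features("AAA", "...")
  expect_equal(sum(v), 1)
  expect_equal(v[["A.000"]], 1)

  v <- triplet_features("GCG", "(.)")
  expect_equal(v[["C.101"]], 1)

  expect_error(triplet_features("ACGT", "..."), "mismatch")

  # direct-counting oracle on random sequences
  set.seed(53)
  for (k in 1:10) {
    n <- 100
    s <- rand_seq(n)
    st <- fold_mfe(s)$structure
    v <- triplet_features(s, st)
    expect_equal(sum(v), 1, tolerance = 1e-9)
    # independent recount of one random bucket
    i <- sample(2:(n - 1), 1)
    b <- strsplit(chartr("T", "U", s), "")[[1]][i]
    pat <- paste(as.integer(strsplit(st, "")[[1]][(i - 1):(i + 1)] != "."),
                 collapse = "")
    key <- paste0(b, ".", pat)
    direct <- 0
    for (j in 2:(n - 1)) {
      bj <- strsplit(chartr("T", "U", s), "")[[1]][j]
      pj <- paste(as.integer(strsplit(st, "")[[1]][(j - 1):(j + 1)] != "."),
                  collapse = "")
      if (bj == b && pj == pat) direct <- direct + 1
    }
    expect_equal(v[[key]], direct / (n - 2), tolerance = 1e-9)
  }
})

test_that("dinucleotide shuffling preserves composition and endpoints", {
  set.seed(59)
  for (k in 1:20) {
    s <- rand_seq(sample(20:80, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(sh), nchar(sh)), substr(s, nchar(s), nchar(s)))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
  }
  expect_error(dinucleotide_shuffle("ACG"), "short")
})

test_that("randomization P-values behave at the boundaries", {
  # shuffle-invariant homopolymer: every shuffle ties the observed MFE
  p <- shuffle_pvalue(strrep("A", 30), n = 20, seed = 3)
  expect_equal(p$p, 1)

  # a planted strong hairpin is significantly more stable than its shuffles
  g <- make_genome(200, gc_frac = 0.3, seed = 17)
  ph <- plant_hairpin(g, arm_len = 25, loop_len = 8, n_mismatches = 0,
                      pos = 60, seed = 4, gc_frac = 0.6)
  win <- extract_interval(ph$genome, ph$truth$start, ph$truth$end)
  p <- shuffle_pvalue(win, n = 200, seed = 5)
  expect_lte(p$p, 0.05)

  # n = 1 with a worse-scoring shuffle gives exactly 1/2
  p1 <- shuffle_pvalue(win, n = 1, seed = 6)
  expect_equal(p1$p, 0.5)

  # reproducibility and RNG hygiene
  expect_identical(shuffle_pvalue(win, n = 20, seed = 8)$p,
                   shuffle_pvalue(win, n = 20, seed = 8)$p)
  set.seed(123); before <- runif(1)
  invisible(shuffle_pvalue(win, n = 5, seed = 9))
  set.seed(123)
  expect_identical(runif(1), before)
})

test_that("the rule filter separates planted hairpins from background", {
  model <- fold_model()
  g <- make_genome(200, gc_frac = 0.3, seed = 19)
  ph <- plant_hairpin(g, 25, 8, 0, pos = 60, seed = 7, gc_frac = 0.6)
  win <- extract_interval(ph$genome, ph$truth$start, ph$truth$end)
  fold <- fold_mfe(win, model)
  sp <- shuffle_pvalue(win, model, n = 100, seed = 10)
  expect_equal(classify_candidate(sp$p, fold), "real")

  # a dinucleotide shuffle of the same window loses significance
  set.seed(11)
  sh <- dinucleotide_shuffle(win)
  fold_sh <- fold_mfe(sh, model)
  sp_sh <- shuffle_pvalue(sh, model, n = 100, seed = 12)
  expect_equal(classify_candidate(sp_sh$p, fold_sh), "pseudo")

  # two terminal loops force pseudo regardless of energy
  two_loop <- structure(list(structure = "((((....))))((((....))))",
                             n_paired = 16L, n_terminal_loops = 2L,
                             mfe = -40), class = "fold_result")
  expect_equal(classify_candidate(0.001, two_loop), "pseudo")
})

test_that("mature-arm selection maximizes pairing with a 5'-most tie-break", {
  g <- make_genome(150, gc_frac = 0.3, seed = 23)
  ph <- plant_hairpin(g, 25, 8, 0, pos = 40, seed = 13, gc_frac = 0.6)
  win <- extract_interval(ph$genome, ph$truth$start, ph$truth$end)
  fold <- fold_mfe(win)
  m <- pick_mature(fold, 21)
  expect_equal(m$start, 1L)          # fully paired arm: tie-break to 5' end
  expect_equal(m$end, 21L)
  expect_equal(m$arm, "5p")
  expect_equal(m$n_paired, 21L)
  expect_equal(nchar(m$seq), 21L)

  # open chain has no arm
  open_fold <- structure(list(seq = strrep("A", 30),
                              structure = strrep(".", 30)),
                         class = "fold_result")
  expect_null(pick_mature(open_fold, 21))

  # exhaustive window-scan oracle on a bulged stem
  set.seed(29)
  for (k in 1:5) {
    s <- rand_seq(60, gc = 0.6)
    f <- fold_mfe(s)
    if (f$n_terminal_loops < 1) next
    m <- pick_mature(f, 15)
    if (is.null(m)) next
    paired <- strsplit(f$structure, "")[[1]] != "."
    best <- max(vapply(seq_len(60 - 15 + 1), function(st) {
      # only windows inside an arm count
      loop <- regexpr("\\(\\.*\\)", f$structure)
      ls <- as.integer(loop) + 1L
      le <- as.integer(loop) + attr(loop, "match.length") - 2L
      if (st + 14 <= ls - 1 || st >= le + 1) sum(paired[st:(st + 14)]) else -1L
    }, 1L))
    expect_equal(m$n_paired, best)
  }
})

test_that("fold models round-trip through YAML", {
  m <- fold_model()
  yml <- tempfile(fileext = ".yaml")
  write_fold_model(m, yml)
  m2 <- read_fold_model(yml)
  # YAML serializes numbers at finite precision
  expect_equal(unname(m2$stack), unname(m$stack), tolerance = 1e-6)
  expect_equal(m2$hairpin, m$hairpin, tolerance = 1e-6)
  s <- "GGGGGAAAACCCCC"
  expect_equal(fold_mfe(s, m2)$mfe, fold_mfe(s, m)$mfe, tolerance = 1e-6)
})
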