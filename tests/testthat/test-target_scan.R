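test_that("a perfect complementary site scores 5' weighting exactly", {
  set.seed(201)
  mir <- rand_seq(22, gc = 0.5)
  g <- make_genome(600, gc_frac = 0.2, seed = 202)
  pt <- plant_target(g, mir, "perfect", pos = 301)
  hits <- suppressMessages(complementarity_scan(mir, pt$genome))
  hit <- hits[hits$start == 301, ]
  expect_equal(nrow(hit), 1L)
  # 15 unweighted matches * 5 + 7 seed matches * 5 * 3 = 180
  expect_equal(hit$S, 15 * 5 + 7 * 5 * 3)
  expect_equal(hit$end, 322L)
  expect_equal(hit$strand, "+")
})

test_that("seed mismatches push sites below the score threshold", {
  set.seed(203)
  mir <- rand_seq(22, gc = 0.5)
  site <- strsplit(revcomp(mir), "")[[1]]
  # mismatch miRNA seed positions 3, 5, 7 (site position s pairs p = 22-s+1)
  for (p in c(3, 5, 7)) {
    s <- 22 - p + 1
    site[s] <- setdiff(c("A", "C", "G", "T"),
                       c(site[s], chartr("ACGT", "TGCA",
                                         substr(mir, p, p))))[1]
  }
  g <- make_genome(600, gc_frac = 0.2, seed = 204)
  g <- mitomir:::splice_seq(g, 301, paste(site, collapse = ""))
  hits <- suppressMessages(complementarity_scan(mir, g))
  expect_false(any(hits$start >= 290 & hits$start <= 320))
})

test_that("ungapped scanning matches the per-diagonal brute-force oracle", {
  set.seed(207)
  params <- target_scan_params(allow_gaps = FALSE, min_S = 60)
  for (k in 1:15) {
    mir <- rand_seq(20, gc = 0.5)
    tg <- make_genome(300, gc_frac = 0.5, seed = 210 + k)
    # plant a near-perfect site half the time so scores straddle min_S
    if (k %% 2 == 0) tg <- mitomir:::splice_seq(tg, 101, revcomp(mir))
    hits <- complementarity_scan(mir, tg, params, strands = "+")
    oracle <- oracle_scan_best(mir, tg$seq, params)
    if (oracle >= params$min_S) {
      expect_equal(max(hits$S), oracle)
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
})

test_that("duplex energies obey containment and match enumeration", {
  set.seed(211)
  mir <- rand_seq(15, gc = 0.5)
  perfect <- revcomp(mir)
  dg_perfect <- hybrid_dG(mir, perfect)$dG
  # any single-mismatch variant of the same site is no more stable
  for (k in 1:5) {
    pos <- sample(15, 1)
    v <- strsplit(perfect, "")[[1]]
    v[pos] <- setdiff(c("A", "C", "G", "T"), v[pos])[sample(3, 1)]
    expect_gte(hybrid_dG(mir, paste(v, collapse = ""))$dG, dg_perfect)
  }

  # no pairs possible: dG = 0
  expect_equal(hybrid_dG(strrep("A", 10), strrep("A", 10))$dG, 0)
  expect_equal(hybrid_dG(strrep("A", 10), strrep("A", 10))$pairing,
               strrep(".", 10))

  # exhaustive pairing enumeration on short duplexes
  for (k in 1:25) {
    a <- rand_seq(sample(4:8, 1), gc = 0.6)
    b <- rand_seq(sample(4:8, 1), gc = 0.6)
    expect_equal(hybrid_dG(a, b)$dG, enum_duplex_min(a, b),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("forbidding seed G:U removes wobble pairs from the seed", {
  # miRNA with G at seed position 4; site offers U across from it
  mir <- "AAAGAAAAA"
  site <- strsplit(revcomp(mir), "")[[1]]
  site[9 - 4 + 1] <- "T"        # G:U wobble across miRNA position 4
  site <- paste(site, collapse = "")
  free <- hybrid_dG(mir, site, forbid_seed_GU = FALSE)
  forbidden <- hybrid_dG(mir, site, forbid_seed_GU = TRUE)
  expect_equal(substr(free$pairing, 4, 4), ":")
  expect_false(substr(forbidden$pairing, 4, 4) == ":")
  expect_gte(forbidden$dG, free$dG)
  expect_equal(forbidden$dG, enum_duplex_min(mir, site, forbid_seed_gu = TRUE),
               tolerance = 1e-9)
})

test_that("target prediction recovers planted sites and filters weak ones", {
  set.seed(213)
  mir <- rand_seq(22, gc = 0.5)
  g <- make_genome(1000, gc_frac = 0.2, seed = 214)
  pt <- plant_target(g, mir, "perfect", pos = 501)
  res <- suppressMessages(predict_targets(setNames(mir, "m1"), pt$genome))
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, pt$truth$start)
  expect_equal(res$end, pt$truth$end)
  expect_equal(res$strand, "+")
  expect_true(res$S >= 150 && res$dG <= -25)

  # heavily mismatched site fails at defaults
  pw <- plant_target(g, mir, "weak", pos = 501, seed = 7)
  resw <- suppressMessages(predict_targets(setNames(mir, "m1"), pw$genome))
  expect_false(any(resw$start >= 480 & resw$start <= 522))

  # two planted sites -> both recovered
  g2 <- mitomir:::splice_seq(pt$genome, 101, revcomp(mir))
  res2 <- suppressMessages(predict_targets(setNames(mir, "m1"), g2))
  expect_equal(sort(res2$start), c(101L, 501L))

  # empty miRNA set -> empty result
  expect_equal(nrow(suppressMessages(
    predict_targets(character(0), pt$genome))), 0L)
})

test_that("tightening either threshold never adds sites", {
  set.seed(217)
  mir <- rand_seq(22)
  g <- make_genome(800, gc_frac = 0.35, seed = 218)
  g <- mitomir:::splice_seq(g, 301, revcomp(mir))
  base <- suppressMessages(predict_targets(setNames(mir, "m"), g))
  stricter_S <- suppressMessages(predict_targets(
    setNames(mir, "m"), g, target_scan_params(min_S = 200)))
  stricter_dG <- suppressMessages(predict_targets(
    setNames(mir, "m"), g, target_scan_params(dG_cutoff = -45)))
  expect_lte(nrow(stricter_S), nrow(base))
  expect_lte(nrow(stricter_dG), nrow(base))
  huge <- suppressMessages(predict_targets(
    setNames(mir, "m"), g, target_scan_params(min_S = 1e9)))
  expect_equal(nrow(huge), 0L)
})

test_that("scanning the reverse-complemented genome mirrors the site set", {
  set.seed(219)
  mir <- rand_seq(21)
  g <- make_genome(700, gc_frac = 0.3, seed = 220)
  g <- mitomir:::splice_seq(g, 201, revcomp(mir))
  fwd <- suppressMessages(predict_targets(setNames(mir, "m"), g))
  grc <- genome_record(g$id, revcomp(g$seq))
  rev <- suppressMessages(predict_targets(setNames(mir, "m"), grc))
  expect_equal(nrow(fwd), nrow(rev))
  L <- g$length
  mirrored_start <- sort(L - rev$end + 1)
  mirrored_end <- sort(L - rev$start + 1)
  expect_equal(sort(fwd$start), mirrored_start)
  expect_equal(sort(fwd$end), mirrored_end)
  flip <- c(`+` = "-", `-` = "+")
  expect_equal(sort(unname(flip[rev$strand])), sort(fwd$strand))
})
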