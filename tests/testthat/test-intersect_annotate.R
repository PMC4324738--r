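mk_sites <- function(tool, starts, ends, mirnas = NULL) {
  if (is.null(mirnas)) mirnas <- paste0("mir", seq_along(starts))
  site_list(tool, data.frame(mirna_id = mirnas, start = starts, end = ends,
                             stringsAsFactors = FALSE))
}

test_that("overlapping sites from different tools merge into one cluster", {
  a <- mk_sites("toolA", 2403, 2430, "mit3")
  b <- mk_sites("toolB", 2410, 2446, "mit6")
  cl <- cluster_shared_sites(list(a, b))
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$start, 2403)
  expect_equal(cl$clusters$end, 2446)
  expect_equal(cl$clusters$n_tools, 2L)

  # disjoint lists give no shared cluster
  d <- cluster_shared_sites(list(mk_sites("toolA", 10, 30),
                                 mk_sites("toolB", 100, 130)))
  expect_equal(nrow(d$clusters), 0L)

  # adjacent but non-overlapping intervals do not link (overlap >= 1 nt)
  e <- cluster_shared_sites(list(mk_sites("toolA", 10, 20),
                                 mk_sites("toolB", 21, 30)))
  expect_equal(nrow(e$clusters), 0L)
})

test_that("three mutually overlapping sites count toward the triple", {
  a <- mk_sites("toolA", c(100, 500), c(130, 530))
  b <- mk_sites("toolB", c(110, 505), c(140, 525))
  c3 <- mk_sites("toolC", c(120, 510), c(150, 535))
  v <- venn_summary(list(a, b, c3))
  expect_equal(v$triple_clusters, 2L)
  expect_equal(unname(v$per_tool), c(2L, 2L, 2L))
  expect_true(all(v$pairwise_clusters >= v$triple_clusters))
})

test_that("the venn summary is permutation-invariant and conserves counts", {
  set.seed(401)
  lists <- lapply(c("A", "B", "C"), function(t) {
    st <- sort(sample(1:2000, 8))
    mk_sites(t, st, st + sample(18:40, 8, replace = TRUE))
  })
  v1 <- venn_summary(lists)
  v2 <- venn_summary(rev(lists))
  expect_equal(v1$per_tool, v2$per_tool)
  expect_equal(sort(unname(v1$pairwise_clusters)),
               sort(unname(v2$pairwise_clusters)))
  expect_equal(v1$triple_clusters, v2$triple_clusters)

  # conservation: clustered members + unclustered sites = total sites
  cl <- cluster_shared_sites(lists)
  total <- sum(vapply(lists, nrow, 1L))
  expect_equal(sum(cl$members$cluster > 0) + sum(cl$members$cluster == 0),
               total)
  if (nrow(cl$clusters))
    expect_equal(sum(cl$clusters$n_members), sum(cl$members$cluster > 0))
})

test_that("gene annotation reproduces the boundary-sharing worked example", {
  gm <- mt_gene_map()
  hits <- annotate_genes(data.frame(start = 9184, end = 9222), gm)
  genes <- hits$gene[hits$gene != "intergenic"]
  expect_equal(sort(genes), c("MT-ATP6", "MT-CO3"))
  expect_equal(hits$overlap_nt[hits$gene == "MT-ATP6"], 24L)
  expect_equal(hits$overlap_nt[hits$gene == "MT-CO3"], 16L)

  # the shared cluster lies fully inside MT-RNR2
  hits2 <- annotate_genes(data.frame(start = 2403, end = 2446), gm)
  expect_equal(hits2$gene, "MT-RNR2")
  expect_equal(hits2$overlap_nt, 2446 - 2403 + 1)

  # a site outside all genes is labeled intergenic
  hits3 <- annotate_genes(data.frame(start = 16000, end = 16030), gm)
  expect_equal(hits3$gene, "intergenic")
  expect_equal(hits3$overlap_nt, 0L)
})

test_that("gene annotation agrees with an all-pairs interval scanner", {
  set.seed(403)
  gm <- data.frame(name = paste0("g", 1:10),
                   start = sort(sample(1:5000, 10)))
  gm$end <- gm$start + sample(50:400, 10, replace = TRUE)
  gm$strand <- "H"; gm$description <- ""
  sites <- data.frame(start = sample(1:5000, 30))
  sites$end <- sites$start + sample(10:60, 30, replace = TRUE)
  ann <- annotate_genes(sites, gm)
  for (k in seq_len(nrow(sites))) {
    expected <- gm$name[gm$start <= sites$end[k] & gm$end >= sites$start[k]]
    got <- ann$gene[ann$start == sites$start[k] & ann$end == sites$end[k]]
    if (!length(expected)) expect_equal(got, "intergenic")
    else expect_setequal(got[got != "intergenic"], expected)
  }
})

test_that("disease annotation separates regulated from unregulated genes", {
  gm <- mt_gene_map()
  sites <- data.frame(mirna_id = c("hsa-miR-mit3", "hsa-miR-mit4", "hsa-miR-mit3"),
                      start = c(3237, 2410, 9186), end = c(3260, 2446, 9206),
                      stringsAsFactors = FALSE)
  hits <- annotate_genes(sites, gm)
  dm <- list("Diabetes mellitus and deafness" = "MT-TL1",
             "Alzheimer disease" = "MT-RNR2",
             "No-site disease" = "MT-CO3",
             "Ghost disease" = "NOT-A-GENE")
  expect_message(rep <- annotate_diseases(hits, dm, gm), "NOT-A-GENE")
  expect_true(rep$regulated[rep$disease == "Diabetes mellitus and deafness"])
  expect_true(rep$regulated[rep$disease == "Alzheimer disease"])
  expect_false(rep$regulated[rep$disease == "No-site disease"])
  expect_equal(attr(rep, "unresolved"), "NOT-A-GENE")

  # a gene regulated by two distinct miRNAs lists both
  sites2 <- data.frame(mirna_id = c("mitA", "mitB"),
                       start = c(1700, 2500), end = c(1725, 2530),
                       stringsAsFactors = FALSE)
  rep2 <- annotate_diseases(annotate_genes(sites2, gm),
                            list(AD = "MT-RNR2"), gm)
  expect_equal(rep2$mirnas, "mitA,mitB")
  expect_equal(rep2$n_sites, 2L)
})

test_that("interaction-map edges conserve total site counts", {
  a <- mk_sites("toolA", c(10, 50, 90, 200, 300, 400, 500),
                c(30, 70, 110, 220, 320, 420, 520),
                mirnas = rep("mirX", 7))
  edges <- interaction_map(list(a), genome_id = "mt")
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$count, 7L)

  expect_equal(nrow(interaction_map(list())), 0L)

  set.seed(407)
  lists <- lapply(c("A", "B"), function(t)
    mk_sites(t, sample(1:1000, 5), sample(1001:1100, 5),
             mirnas = sample(c("m1", "m2"), 5, replace = TRUE)))
  edges <- interaction_map(lists)
  expect_equal(sum(edges$count), 10L)

  dot <- tempfile(fileext = ".dot")
  write_interaction_dot(edges, dot)
  expect_true(any(grepl("digraph", readLines(dot))))
})
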