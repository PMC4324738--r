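test_that("FASTA reading normalizes the alphabet and validates structure", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT"), fa)
  g <- read_genome_fasta(fa)
  expect_equal(g$id, "x")
  expect_equal(g$seq, "ACGT")
  expect_equal(g$length, 4L)

  writeLines(c(">r", "acguACGU"), fa)
  g <- read_genome_fasta(fa)
  expect_equal(g$seq, "ACGTACGT")   # u/U -> T, case folded
  expect_equal(g$length, 8L)

  writeLines(c(">a", "ACGT", ">b", "GGCC"), fa)
  expect_error(read_genome_fasta(fa), "multi-record")
  expect_equal(read_genome_fasta(fa, id = "b")$seq, "GGCC")

  writeLines(c(">e", ""), fa)
  expect_error(read_genome_fasta(fa), "empty")
})

test_that("FASTA writing round-trips sequence content exactly", {
  g <- make_genome(500, gc_frac = 0.5, seed = 11, id = "rt")
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$id, g$id)
  # RNA emission writes U, reading normalizes back
  write_genome_fasta(g, fa, rna = TRUE)
  raw <- paste(readLines(fa)[-1], collapse = "")
  expect_false(grepl("T", raw, fixed = TRUE))
  expect_identical(read_genome_fasta(fa)$seq, g$seq)
})

test_that("interval extraction honors strand, bounds and circular wrap", {
  g <- genome_record("g", "ACGTACGT")
  expect_equal(extract_interval(g, 2, 4), "CGT")
  expect_equal(extract_interval(g, 2, 4, strand = "-"), revcomp("CGT"))
  expect_error(extract_interval(g, 7, 10), "out of range")
  expect_error(extract_interval(g, 0, 3), "invalid")

  gc <- genome_record("c", "ACGT", circular = TRUE)
  expect_error(extract_interval(gc, 3, 6), "out of range")  # wrap not requested
  expect_equal(extract_interval(gc, 3, 6, wrap = TRUE), "GTAC")
  # brute-force rotation oracle on random circular genomes
  set.seed(5)
  for (k in 1:20) {
    seq <- rand_seq(sample(10:30, 1))
    gk <- genome_record("k", seq, circular = TRUE)
    L <- nchar(seq)
    st <- sample(seq_len(L), 1); len <- sample(seq_len(L), 1)
    doubled <- paste0(seq, seq)
    expect_equal(extract_interval(gk, st, st + len - 1, wrap = TRUE),
                 substr(doubled, st, st + len - 1))
  }
})

test_that("extracted length always equals the interval length", {
  set.seed(9)
  g <- make_genome(300, seed = 2)
  for (k in 1:50) {
    st <- sample(1:250, 1); en <- st + sample(0:49, 1)
    strand <- sample(c("+", "-"), 1)
    expect_equal(nchar(extract_interval(g, st, en, strand)), en - st + 1)
  }
})

test_that("reverse complement is an involution", {
  set.seed(21)
  for (k in 1:30) {
    s <- rand_seq(sample(1:80, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("gene maps load sorted, keep boundary-sharing genes, and report bad rows", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend\tstrand\tdescription",
               "MT-CO3\t9207\t9990\tH\tcox3",
               "MT-ATP6\t8527\t9207\tH\tatp6",
               "MT-RNR2\t1671\t3229\tH\trRNA"), tsv)
  gm <- read_gene_map(tsv)
  expect_equal(gm$name, c("MT-RNR2", "MT-ATP6", "MT-CO3"))
  expect_equal(gm$start[gm$name == "MT-RNR2"], 1671L)
  expect_equal(gm$end[gm$name == "MT-RNR2"], 3229L)
  # MT-ATP6 and MT-CO3 share position 9207 and both load
  expect_equal(sum(gm$start <= 9207 & gm$end >= 9207), 2L)

  writeLines(c("name\tstart\tend\tstrand\tdescription",
               "BAD\t100\t50\tH\tx"), tsv)
  expect_error(read_gene_map(tsv), "line 2")

  writeLines(character(0), tsv)
  expect_warning(gm0 <- read_gene_map(tsv), "empty")
  expect_equal(nrow(gm0), 0L)
})

test_that("BED and GFF3 exports use the standard coordinate conventions", {
  df <- data.frame(start = c(10L, 100L), end = c(20L, 150L),
                   strand = c("+", "-"))
  bed <- tempfile(fileext = ".bed")
  export_bed(df, "chrM", bed, name = c("a", "b"))
  fields <- strsplit(readLines(bed), "\t")
  expect_equal(as.integer(fields[[1]][2]), 9L)    # BED 0-based start
  expect_equal(as.integer(fields[[1]][3]), 20L)   # half-open end
  gff <- tempfile(fileext = ".gff3")
  export_gff3(df, "chrM", gff)
  rows <- readLines(gff)
  rows <- rows[!grepl("^#", rows)]
  f1 <- strsplit(rows[1], "\t")[[1]]
  expect_equal(as.integer(f1[4]), 10L)            # GFF3 1-based inclusive
  expect_equal(as.integer(f1[5]), 20L)
})
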