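#' Bundled mitochondrial miRNA binding-site coordinates
#'
#' The published binding-site start/end coordinates of the six predicted
#' mitochondrial miRNAs in human and their homologs in chimp, orangutan,
#' mouse and rat (long format; a searched organism with no homolog for a
#' miRNA keeps a row with NA coordinates, so absences are explicit).
#' Coordinates are 1-based inclusive.
#'
#' @return data.frame with columns `mirna`, `organism`, `start`, `end`.
#' @export
mt_binding_sites <- function() {
  df <- utils::read.delim(system.file("extdata", "mt_mirna_sites.tsv",
                                      package = "mitomir"),
                          stringsAsFactors = FALSE, na.strings = c("NA", "-"))
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df
}

#' Homolog counts per organism from a long-format binding-site table
#'
#' Counts rows with non-missing coordinates per non-reference organism;
#' searched organisms whose rows are all NA report an explicit zero.
#'
#' @param sites data.frame as returned by [mt_binding_sites()].
#' @param reference organism to exclude (the query species).
#' @return List: `per_organism` named integer vector and `total`.
#' @export
homolog_counts <- function(sites = mt_binding_sites(), reference = "human") {
  organisms <- setdiff(unique(sites$organism), reference)
  per <- vapply(organisms, function(o)
    sum(sites$organism == o & !is.na(sites$start)), 1L)
  list(per_organism = per, total = sum(per))
}

#' Bundled mitochondrial gene map (published coordinates)
#'
#' The gene intervals used by the annotation examples: MT-RNR2 (1671-3229),
#' MT-ATP6 (8527-9207), MT-CO3 (9207-9990) as published, plus MT-TL1
#' (3230-3304, MITOMAP reference coordinates).  MT-ATP6 and MT-CO3 share
#' boundary position 9207.
#'
#' @return data.frame from [read_gene_map()].
#' @export
mt_gene_map <- function() {
  read_gene_map(system.file("extdata", "mt_gene_map.tsv", package = "mitomir"))
}

#' Bundled mitochondrial disease-to-gene table
#'
#' Disease/disorder to gene-symbol mapping for the annotation examples
#' (LHON, Leigh syndrome, MELAS, Alzheimer disease, diabetes-deafness,
#' diabetes-myopathy).
#'
#' @return Named list from [read_disease_map()].
#' @export
mt_disease_map <- function() {
  read_disease_map(system.file("extdata", "mt_disease_map.tsv",
                               package = "mitomir"))
}
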