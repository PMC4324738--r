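#' Bundle a per-tool target-site list
#'
#' @param tool tool label (unique within a comparison).
#' @param sites data.frame with at least `mirna_id`, `start`, `end`.
#' @return data.frame of sites sorted by start, carrying a `tool` column.
#' @export
site_list <- function(tool, sites) {
  stopifnot(is.character(tool), length(tool) == 1L)
  need <- c("mirna_id", "start", "end")
  if (!all(need %in% names(sites)))
    stop("sites need columns: ", paste(need, collapse = ", "))
  sites$tool <- tool
  sites <- sites[order(sites$start, sites$end), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# bind a list of site lists into one frame with unique tool labels
bind_site_lists <- function(lists) {
  if (!length(lists))
    return(data.frame(tool = character(), mirna_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(lists, function(x)
    x[, c("tool", "mirna_id", "start", "end")]))
  rownames(df) <- NULL
  df
}

#' Cluster shared binding sites across tools
#'
#' Single-linkage clustering of target-site intervals pooled across tools:
#' two sites link when they overlap by at least `min_overlap` nt; each
#' cluster's interval is the union (span) of its members.  Only clusters
#' with members from at least two distinct tools are reported as shared.
#'
#' @param lists list of site data.frames (each with a `tool` column, e.g.
#'   from [site_list()] or [predict_targets()]).
#' @param min_overlap minimum overlap in nt to link two sites (default 1).
#' @return List with `clusters` (data.frame: cluster id, start, end,
#'   n_members, n_tools, tools, mirnas) and `members` (per-site cluster
#'   assignment; cluster 0 = unclustered or single-tool).
#' @export
cluster_shared_sites <- function(lists, min_overlap = 1L) {
  stopifnot(length(lists) >= 2L)
  df <- bind_site_lists(lists)
  if (nrow(df) == 0L)
    return(list(clusters = data.frame(), members = df))
  ir <- IRanges::IRanges(start = df$start, end = df$end)
  # single-linkage components under "overlap >= min_overlap"
  hits <- IRanges::findOverlaps(ir, ir, minoverlap = min_overlap)
  g <- seq_len(nrow(df))                   # union-find
  find <- function(x) { while (g[x] != x) { g[x] <<- g[g[x]]; x <- g[x] }; x }
  for (h in seq_along(hits)) {
    a <- find(S4Vectors::queryHits(hits)[h])
    b <- find(S4Vectors::subjectHits(hits)[h])
    if (a != b) g[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(nrow(df)), find, 1L)
  df$component <- match(comp, sort(unique(comp)))

  clusters <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$component),
                                    function(idx) {
    tools <- unique(df$tool[idx])
    data.frame(start = min(df$start[idx]), end = max(df$end[idx]),
               n_members = length(idx), n_tools = length(tools),
               tools = paste(sort(tools), collapse = ","),
               mirnas = paste(df$mirna_id[idx], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  shared <- clusters$n_tools >= 2L
  members <- df
  members$cluster <- ifelse(shared[df$component],
                            match(df$component, which(shared)), 0L)
  clusters <- clusters[shared, , drop = FALSE]
  if (nrow(clusters)) {
    clusters$cluster <- seq_len(nrow(clusters))
    clusters <- clusters[, c("cluster", "start", "end", "n_members",
                             "n_tools", "tools", "mirnas")]
    rownames(clusters) <- NULL
  }
  list(clusters = clusters, members = members)
}

#' Multi-tool intersection summary
#'
#' Per-tool site counts, pairwise shared counts, and the triple count,
#' counted two ways (the counting rule for "shared sites" is ambiguous in
#' narrative descriptions, so both are exported): at cluster level (shared
#' clusters whose members cover the pair / all three tools) and at site
#' level (sites of one tool overlapping any site of the other).
#'
#' @param lists list of per-tool site data.frames.
#' @param min_overlap minimum overlap in nt (default 1).
#' @return List of class `venn_summary`: `per_tool`, `pairwise_clusters`,
#'   `triple_clusters`, `pairwise_sites`, `clusters`.
#' @export
venn_summary <- function(lists, min_overlap = 1L) {
  stopifnot(length(lists) >= 2L)
  df <- bind_site_lists(lists)
  tools <- sort(unique(df$tool))
  per_tool <- vapply(tools, function(t) sum(df$tool == t), 1L)

  cl <- cluster_shared_sites(lists, min_overlap)
  pairs <- utils::combn(tools, 2L, simplify = FALSE)
  pw_cl <- vapply(pairs, function(p) {
    if (!nrow(cl$clusters)) return(0L)
    sum(vapply(strsplit(cl$clusters$tools, ","), function(ts)
      all(p %in% ts), TRUE))
  }, 1L)
  names(pw_cl) <- vapply(pairs, paste, "", collapse = "&")
  triple <- if (length(tools) >= 3L && nrow(cl$clusters))
    sum(cl$clusters$n_tools == length(tools)) else 0L

  # site-level pairwise: sites of tool A overlapping >= 1 site of tool B
  pw_site <- vapply(pairs, function(p) {
    a <- df[df$tool == p[1L], ]; b <- df[df$tool == p[2L], ]
    if (!nrow(a) || !nrow(b)) return(0L)
    ov <- IRanges::countOverlaps(IRanges::IRanges(a$start, a$end),
                                 IRanges::IRanges(b$start, b$end),
                                 minoverlap = min_overlap)
    sum(ov > 0L)
  }, 1L)
  names(pw_site) <- names(pw_cl)

  structure(list(per_tool = per_tool,
                 pairwise_clusters = pw_cl,
                 triple_clusters = as.integer(triple),
                 pairwise_sites = pw_site,
                 clusters = cl$clusters),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("per-tool sites: ",
      paste(names(x$per_tool), x$per_tool, sep = "=", collapse = ", "), "\n")
  cat("pairwise shared clusters: ",
      paste(names(x$pairwise_clusters), x$pairwise_clusters, sep = "=",
            collapse = ", "), "\n")
  cat("triple shared clusters:", x$triple_clusters, "\n")
  invisible(x)
}

#' Annotate sites or clusters against a gene map
#'
#' 1-based inclusive interval intersection; a site may overlap several genes
#' (genes sharing a boundary position both count when the site covers it);
#' sites outside every gene are labeled intergenic.
#'
#' @param sites data.frame with `start`, `end` (clusters or target sites).
#' @param gene_map data.frame from [read_gene_map()].
#' @return data.frame, one row per (site, gene) overlap, or one `intergenic`
#'   row for sites hitting no gene; columns include `overlap_nt`.
#' @export
annotate_genes <- function(sites, gene_map) {
  if (!nrow(sites))
    return(data.frame(start = integer(), end = integer(), gene = character(),
                      overlap_nt = integer(), stringsAsFactors = FALSE))
  s_ir <- IRanges::IRanges(sites$start, sites$end)
  g_ir <- IRanges::IRanges(gene_map$start, gene_map$end)
  hits <- IRanges::findOverlaps(s_ir, g_ir)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rows <- list()
  for (k in seq_len(nrow(sites))) {
    genes_k <- sh[qh == k]
    base <- sites[k, , drop = FALSE]
    rownames(base) <- NULL
    if (!length(genes_k)) {
      r <- base; r$gene <- "intergenic"; r$overlap_nt <- 0L
      rows[[length(rows) + 1L]] <- r
    } else {
      for (gk in genes_k) {
        r <- base
        r$gene <- gene_map$name[gk]
        r$overlap_nt <- min(sites$end[k], gene_map$end[gk]) -
          max(sites$start[k], gene_map$start[gk]) + 1L
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Disease regulation report
#'
#' For each disease: which member genes carry at least one binding site and
#' which carry none; per regulated gene, the contributing miRNAs and
#' coordinates.  Gene symbols that do not resolve against the gene map are
#' logged and skipped.
#'
#' @param gene_hits data.frame from [annotate_genes()] run on target sites
#'   (needs a `mirna_id` column for per-miRNA detail; optional).
#' @param disease_map named list from [read_disease_map()].
#' @param gene_map data.frame from [read_gene_map()] (to resolve symbols).
#' @return data.frame, one row per (disease, gene): `disease`, `gene`,
#'   `regulated`, `n_sites`, `mirnas`; plus attribute `unresolved` listing
#'   skipped symbols.
#' @export
annotate_diseases <- function(gene_hits, disease_map, gene_map) {
  unresolved <- character(0)
  rows <- list()
  for (disease in names(disease_map)) {
    for (gene in disease_map[[disease]]) {
      if (!gene %in% gene_map$name) {
        unresolved <- c(unresolved, gene)
        next
      }
      hk <- gene_hits[gene_hits$gene == gene, , drop = FALSE]
      mirnas <- if ("mirna_id" %in% names(hk)) unique(hk$mirna_id) else character(0)
      rows[[length(rows) + 1L]] <- data.frame(
        disease = disease, gene = gene,
        regulated = nrow(hk) > 0L, n_sites = nrow(hk),
        mirnas = paste(sort(mirnas), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(unresolved))
    message("unresolved gene symbol(s) skipped: ",
            paste(unique(unresolved), collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease = character(), gene = character(),
               regulated = logical(), n_sites = integer(),
               mirnas = character(), stringsAsFactors = FALSE)
  attr(out, "unresolved") <- unique(unresolved)
  out
}

#' Interaction-map edge list
#'
#' One edge per (miRNA, genome, tool) with the number of predicted target
#' sites as weight; edge weights sum to the total site count.
#'
#' @param lists list of per-tool site data.frames.
#' @param genome_id label for the target genome.
#' @return data.frame `mirna_id`, `genome`, `tool`, `count`.
#' @export
interaction_map <- function(lists, genome_id = "genome") {
  df <- bind_site_lists(lists)
  if (!nrow(df))
    return(data.frame(mirna_id = character(), genome = character(),
                      tool = character(), count = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(count = df$start),
                          by = list(mirna_id = df$mirna_id, tool = df$tool),
                          FUN = length)
  agg$genome <- genome_id
  agg <- agg[order(agg$tool, agg$mirna_id), c("mirna_id", "genome", "tool", "count")]
  rownames(agg) <- NULL
  agg
}

#' Export an interaction map as Graphviz DOT
#'
#' @param edges data.frame from [interaction_map()].
#' @param path output file.
#' @export
write_interaction_dot <- function(edges, path) {
  lines <- c("digraph interaction_map {")
  for (k in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s (%d)"];',
                              edges$mirna_id[k], edges$genome[k],
                              edges$tool[k], edges$count[k]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
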