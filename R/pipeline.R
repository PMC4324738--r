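#' Default pipeline configuration
#'
#' One configuration object governs every stage threshold; any run writes
#' the resolved configuration into its manifest so results are reproducible
#' from the manifest alone.  Defaults follow the classical parameterization
#' of each stage: einverted-style repeat scoring (match 3, mismatch -4, gap
#' 12, threshold 10, extent 500), a 60-150 nt window band targeting ~120-nt
#' precursors, the rule filter (MFE <= -18 kcal/mol, shuffle P <= 0.05,
#' single hairpin), mature length 21 (19-22 accepted), and the two-phase
#' target scan (S >= 150, dG <= -25 kcal/mol, w = 3, seed 2-8).
#'
#' @return Nested list of stage settings.
#' @export
default_config <- function() {
  list(
    repeats = list(match = 3L, mismatch = -4L, gap_penalty = 12L,
                   min_score = 10L, max_extent = 500L),
    span_band = c(60L, 150L),
    rules = list(mfe_max = -18, p_max = 0.05, min_stem_pairs = 16L,
                 loop_range = c(3L, 30L)),
    mature_length = 21L,
    mature_range = c(19L, 22L),
    shuffle_n = 200L,
    seed = 1L,
    targets = list(gap_open = 2.0, gap_extend = 8.0, min_S = 150.0,
                   dG_cutoff = -25.0, w = 3.0, seed_range = c(2L, 8L),
                   match_score = 5.0, wobble_score = 1.0,
                   mismatch_score = -3.0, forbid_seed_GU = FALSE))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  cfg
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

new_manifest <- function(stage, config, counts, seed) {
  list(stage = stage,
       tool = paste0("mitomir ", as.character(utils::packageVersion("mitomir"))),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, counts = counts, config = config)
}

#' Discover pre-miRNA / mature miRNA candidates in a genome
#'
#' Full discovery chain: inverted repeats -> ~120-nt hairpin windows ->
#' MFE fold -> triplet features, normalized MFE and shuffle P-value ->
#' rule classification -> mature-arm selection -> physicochemical report.
#' Counts are monotone along the chain (windows <= repeats, candidates <=
#' windows).
#'
#' @param genome a [genome_record()].
#' @param config configuration list (see [default_config()]).
#' @param model a [fold_model()].
#' @return List: `repeats`, `windows`, `candidates` (per-window fold +
#'   features + verdict), `matures` (data.frame of accepted mature arms
#'   with physicochemical properties), `manifest`.
#' @export
run_discover <- function(genome, config = default_config(),
                         model = fold_model()) {
  rp <- do.call(repeat_params, config$repeats)
  repeats <- find_inverted_repeats(genome, rp)
  windows <- select_windows(repeats, genome, config$span_band)

  candidates <- list()
  matures <- list()
  if (nrow(windows)) {
    for (k in seq_len(nrow(windows))) {
      seq_k <- windows$seq[k]
      fold <- fold_mfe(seq_k, model)
      sp <- shuffle_pvalue(seq_k, model, n = config$shuffle_n,
                           seed = config$seed + k)
      feats <- list(triplet = triplet_features(seq_k, fold$structure),
                    mfe = fold$mfe,
                    amfe = 100 * fold$mfe / nchar(seq_k),
                    shuffle_p = sp$p, n_shuffles = sp$n,
                    rng_seed = sp$seed)
      verdict <- classify_candidate(feats, fold, do.call(candidate_rules,
                                                         config$rules))
      mature <- NULL
      if (verdict == "real") {
        mature <- pick_mature(fold, config$mature_length)
        if (is.null(mature)) verdict <- "pseudo"
      }
      candidates[[k]] <- list(window = windows[k, c("start", "end")],
                              seq = seq_k, fold = fold, features = feats,
                              verdict = verdict, mature = mature)
      if (verdict == "real") {
        pc <- physchem_report(stats::setNames(mature$seq, "m"))
        matures[[length(matures) + 1L]] <- data.frame(
          window_start = windows$start[k], window_end = windows$end[k],
          mature_start = windows$start[k] + mature$start - 1L,
          mature_end = windows$start[k] + mature$end - 1L,
          arm = mature$arm, seq = mature$seq,
          mfe = fold$mfe, shuffle_p = sp$p,
          gc_pct = pc$gc_pct, au_pct = pc$au_pct,
          mw_g_mol = pc$mw_g_mol, dG_kcal_mol = pc$dG_kcal_mol,
          stringsAsFactors = FALSE)
      }
    }
  }
  matures <- if (length(matures)) do.call(rbind, matures) else
    data.frame(window_start = integer(), window_end = integer(),
               mature_start = integer(), mature_end = integer(),
               arm = character(), seq = character(), mfe = numeric(),
               shuffle_p = numeric(), gc_pct = numeric(), au_pct = numeric(),
               mw_g_mol = numeric(), dG_kcal_mol = numeric(),
               stringsAsFactors = FALSE)

  counts <- list(repeats = nrow(repeats), windows = nrow(windows),
                 candidates = sum(vapply(candidates, function(x)
                   x$verdict == "real", TRUE)))
  stopifnot(counts$windows <= counts$repeats,
            counts$candidates <= counts$windows)
  list(repeats = repeats, windows = windows, candidates = candidates,
       matures = matures,
       manifest = new_manifest("discover", config, counts, config$seed))
}

#' Predict target sites for a set of mature miRNAs
#'
#' @param mirnas named character vector or miRNA FASTA path.
#' @param genome a [genome_record()].
#' @param config configuration list.
#' @param model a [fold_model()].
#' @param tool tool label for the emitted sites.
#' @return List: `sites` data.frame and `manifest`.
#' @export
run_targets <- function(mirnas, genome, config = default_config(),
                        model = fold_model(), tool = "miranda-like") {
  tp <- do.call(target_scan_params, config$targets)
  sites <- predict_targets(mirnas, genome, tp, model, tool = tool)
  list(sites = sites,
       manifest = new_manifest("targets", config,
                               list(mirnas = length(mirnas),
                                    sites = nrow(sites)), config$seed))
}

#' Intersect and annotate multi-tool site lists
#'
#' @param lists list of per-tool site data.frames.
#' @param gene_map data.frame from [read_gene_map()].
#' @param disease_map named list from [read_disease_map()]; optional.
#' @param genome_id label for interaction-map edges.
#' @param config configuration list.
#' @return List: `venn`, `clusters`, `gene_hits` (per-site gene
#'   annotation), `cluster_genes`, `diseases`, `edges`, `manifest`.
#' @export
run_annotate <- function(lists, gene_map, disease_map = NULL,
                         genome_id = "genome", config = default_config()) {
  stopifnot(length(lists) >= 1L)
  all_sites <- bind_site_lists(lists)
  venn <- NULL; clusters <- data.frame()
  if (length(lists) >= 2L) {
    venn <- venn_summary(lists)
    clusters <- venn$clusters
  }
  gene_hits <- annotate_genes(all_sites, gene_map)
  cluster_genes <- if (nrow(clusters))
    annotate_genes(clusters, gene_map) else data.frame()
  diseases <- if (!is.null(disease_map))
    annotate_diseases(gene_hits, disease_map, gene_map) else NULL
  edges <- interaction_map(lists, genome_id)
  counts <- list(lists = length(lists), sites = nrow(all_sites),
                 clusters = nrow(clusters))
  list(venn = venn, clusters = clusters, gene_hits = gene_hits,
       cluster_genes = cluster_genes, diseases = diseases, edges = edges,
       manifest = new_manifest("annotate", config, counts, config$seed))
}

#' Calibration quantities for a reference mitochondrial genome
#'
#' Computes, from a user-supplied reference genome FASTA, the quantities
#' used to calibrate the discovery stage against a published reference run:
#' genome length, inverted-repeat count under the default scoring, window
#' count under the span band, and the %GC range of the mature sequences
#' extracted at the bundled binding-site coordinates.
#'
#' @param fasta_path path to the reference genome FASTA (e.g. human mtDNA,
#'   NC_012920.1; not bundled - supply a local copy).
#' @param config configuration list.
#' @return List: `genome_length`, `n_inverted_repeats`, `n_windows`,
#'   `mature_gc_range` (named length-2), `mature_lengths`.
#' @export
calibrate_reference <- function(fasta_path, config = default_config()) {
  genome <- read_genome_fasta(fasta_path, circular = TRUE)
  rp <- do.call(repeat_params, config$repeats)
  repeats <- find_inverted_repeats(genome, rp)
  windows <- select_windows(repeats, genome, config$span_band)
  sites <- mt_binding_sites()
  hum <- sites[sites$organism == "human", , drop = FALSE]
  seqs <- vapply(seq_len(nrow(hum)), function(k)
    extract_interval(genome, hum$start[k], hum$end[k]), "")
  gc <- vapply(seqs, function(s) gc_au_content(s)[["gc_pct"]], 0)
  list(genome_length = genome$length,
       n_inverted_repeats = nrow(repeats),
       n_windows = nrow(windows),
       mature_gc_range = c(min = min(round(gc)), max = max(round(gc))),
       mature_lengths = hum$end - hum$start + 1L)
}

#' Write a run manifest as JSON
#' @param manifest manifest list from a `run_*` function.
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
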