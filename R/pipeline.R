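#' Configuration for a full deconvolution pipeline run
#'
#' Bundles every stage parameter with either a simulation configuration
#' (the pipeline then generates its own data) or the path of a fixture
#' bundle on disk. Numeric defaults mirror the stage-level defaults.
#'
#' @param sim A [sim_config()] used when `input_dir` is `NULL`.
#' @param input_dir Optional directory holding a [write_fixture_bundle()]
#'   bundle to analyze instead of simulating.
#' @param out_dir Optional output directory for stage TSVs, the Newick
#'   dendrograms and the JSON run report.
#' @param l_min,i_min,seed_length,min_probes_per_set Probe-masking
#'   parameters, see [score_cross_hybridization()] and [build_mask()].
#' @param normalization `"scale"` (robust median-centering, the default;
#'   see [scale_normalize()]) or `"quantile"` ([quantile_normalize()]).
#' @param summary_method Probeset summary, see [summarize_probesets()].
#' @param alpha,require_same_direction,use_adjusted Consensus rule, see
#'   [intersect_lines()].
#' @param theta,p_max,overlap_method Term-clustering parameters, see
#'   [cluster_and_filter()].
#' @param panel_size Number of consensus genes carried to the count
#'   validation platform.
#' @param concordance_alpha Significance threshold for "validated" calls.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = NULL, l_min = 15, i_min = 0.75,
                            seed_length = 12, min_probes_per_set = 3,
                            normalization = "scale",
                            summary_method = "median", alpha = 0.05,
                            require_same_direction = TRUE,
                            use_adjusted = FALSE, theta = 0.30, p_max = 0.05,
                            overlap_method = "min", panel_size = 30,
                            concordance_alpha = 0.05) {
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 l_min = l_min, i_min = i_min, seed_length = seed_length,
                 min_probes_per_set = min_probes_per_set,
                 normalization = normalization,
                 summary_method = summary_method, alpha = alpha,
                 require_same_direction = require_same_direction,
                 use_adjusted = use_adjusted, theta = theta, p_max = p_max,
                 overlap_method = overlap_method, panel_size = panel_size,
                 concordance_alpha = concordance_alpha),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map to [pipeline_config()] arguments; the optional `sim`
#' block maps to [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  cfg_sim <- if (is.null(sim_args)) sim_config() else do.call(sim_config, sim_args)
  do.call(pipeline_config, c(list(sim = cfg_sim), y))
}

#' Validate a pipeline configuration
#'
#' Checks every cross-field constraint and returns **all** violations, not
#' just the first.
#'
#' @param config A `run_config` object.
#' @param stop_on_error Raise an aggregated error when violations exist
#'   (default); otherwise return them.
#' @return Invisibly, a character vector of violations (empty when valid).
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  in01 <- function(x) is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
  viol <- collect_violations(
    check_that(inherits(config, "run_config"), "config must be a run_config object"),
    check_that(inherits(config$sim, "sim_config"), "sim must be a sim_config object"),
    check_that(in01(config$theta), "theta must lie in [0, 1]"),
    check_that(in01(config$p_max), "p_max must lie in [0, 1]"),
    check_that(in01(config$alpha) && config$alpha > 0, "alpha must lie in (0, 1]"),
    check_that(in01(config$concordance_alpha) && config$concordance_alpha > 0,
               "concordance_alpha must lie in (0, 1]"),
    check_that(in01(config$i_min), "i_min must lie in [0, 1]"),
    check_that(is.numeric(config$l_min) && config$l_min >= 1,
               "l_min must be a positive match length"),
    check_that(!inherits(config$sim, "sim_config") ||
                 config$l_min <= config$sim$probe_length,
               "l_min must not exceed the probe length"),
    check_that(is.numeric(config$seed_length) && config$seed_length >= 4 &&
                 config$seed_length <= 31,
               "seed_length must lie in [4, 31]"),
    check_that(is.numeric(config$min_probes_per_set) &&
                 config$min_probes_per_set >= 1,
               "min_probes_per_set must be >= 1"),
    check_that(config$normalization %in% c("scale", "quantile"),
               "normalization must be 'scale' or 'quantile'"),
    check_that(config$summary_method %in% c("median", "medianpolish"),
               "summary_method must be 'median' or 'medianpolish'"),
    check_that(config$overlap_method %in% c("min", "jaccard"),
               "overlap_method must be 'min' or 'jaccard'"),
    check_that(is.numeric(config$panel_size) && config$panel_size >= 1,
               "panel_size must be >= 1")
  )
  if (!is.null(config$input_dir)) {
    needed <- c("probes_human.fasta", "probes_mouse.fasta",
                "probe_annotation.tsv", "transcripts_human.fasta",
                "transcripts_mouse.fasta", "intensity_human.tsv",
                "intensity_mouse.tsv", "sample_sheet.tsv")
    for (f in needed) {
      path <- file.path(config$input_dir, f)
      if (!file.exists(path))
        viol <- c(viol, paste0("input file missing: ", f, " (", path, ")"))
    }
  }
  if (length(viol) && stop_on_error)
    stop("invalid pipeline configuration:\n  - ",
         paste(viol, collapse = "\n  - "), call. = FALSE)
  invisible(viol)
}

#' Run the full deconvolution pipeline
#'
#' Executes simulate (or load) -> mask -> normalize/summarize -> per-line
#' differential expression -> cross-line consensus -> clustering diagnostic
#' -> gene-set enrichment with overlap clustering -> crosstalk inference ->
#' count-platform concordance, for both species' compartments, and returns
#' a machine-readable run report. Reruns with the same configuration are
#' deterministic.
#'
#' @param config A `run_config` from [pipeline_config()] or
#'   [read_run_config()].
#' @return A list of class `run_report` with `counts` (per-stage summary
#'   numbers), `params`, `seed`, `files` (when `out_dir` is set),
#'   `wall_time_s`, and `results` (the in-memory stage objects).
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  t0 <- Sys.time()

  if (is.null(config$input_dir)) {
    sim <- simulate_experiment(config$sim, generate_references(config$sim))
    gs <- build_gene_sets(sim)
    ref <- build_interaction_reference(sim)
    data <- list(intensity = list(human = sim$intensity_human,
                                  mouse = sim$intensity_mouse),
                 probe_design = sim$probe_design,
                 transcripts = list(human = sim$transcripts_human,
                                    mouse = sim$transcripts_mouse),
                 sample_sheet = sim$sample_sheet,
                 gene_sets = gs,
                 interactions = ref$interactions, orthology = ref$orthology,
                 truth = sim$truth)
    count_source <- sim
  } else {
    b <- read_fixture_bundle(config$input_dir)
    data <- list(intensity = list(human = b$intensity_human,
                                  mouse = b$intensity_mouse),
                 probe_design = b$probe_design,
                 transcripts = list(human = b$transcripts_human,
                                    mouse = b$transcripts_mouse),
                 sample_sheet = b$sample_sheet,
                 gene_sets = list(
                   human = list(sets = b$gene_sets_human,
                                universe = b$truth$de_genes_human$gene_id),
                   mouse = list(sets = b$gene_sets_mouse,
                                universe = b$truth$de_genes_mouse$gene_id)),
                 interactions = b$interactions, orthology = b$orthology,
                 truth = b$truth)
    bl <- b$truth$baselines
    count_source <- structure(list(
      truth = list(
        de_genes_human = b$truth$de_genes_human,
        de_genes_mouse = b$truth$de_genes_mouse,
        baseline_human = setNames(bl$baseline_log2[bl$species == "human"],
                                  bl$gene_id[bl$species == "human"]),
        baseline_mouse = setNames(bl$baseline_log2[bl$species == "mouse"],
                                  bl$gene_id[bl$species == "mouse"])),
      sample_sheet = b$sample_sheet, config = config$sim), class = "xeno_sim")
  }

  sheet <- data$sample_sheet
  lines <- unique(sheet$line)
  species_res <- list()
  for (sp in c("human", "mouse")) {
    stage <- sprintf("[%s]", sp)
    foreign <- if (sp == "human") data$transcripts$mouse else data$transcripts$human
    design <- data$probe_design[data$probe_design$species == sp, , drop = FALSE]
    report <- score_cross_hybridization(design, foreign, l_min = config$l_min,
                                        i_min = config$i_min,
                                        seed_length = config$seed_length)
    mask <- build_mask(report, design,
                       min_probes_per_set = config$min_probes_per_set)
    masked <- apply_mask(data$intensity[[sp]], mask)
    normalize <- if (config$normalization == "quantile") quantile_normalize
                 else scale_normalize
    expr <- summarize_probesets(normalize(masked), design,
                                method = config$summary_method)
    ctr <- if (sp == "human") "B-vs-A" else "B-vs-C"
    de <- lapply(lines, function(l)
      region_contrast(expr, sheet, contrast = ctr, species = sp, line = l))
    names(de) <- lines
    if (length(lines) != 2)
      stop(stage, " consensus intersection expects exactly 2 lines, got ",
           length(lines))
    consensus <- intersect_lines(de[[1]], de[[2]], alpha = config$alpha,
                                 require_same_direction = config$require_same_direction,
                                 use_adjusted = config$use_adjusted)
    clus <- NULL
    if (nrow(consensus) >= 2) {
      sub <- expr[rownames(expr) %in% consensus$feature_id, , drop = FALSE]
      labs <- sheet$region[match(colnames(sub), sheet$sample_id)]
      clus <- cluster_samples(sub, labs)
    }
    coll <- data$gene_sets[[sp]]
    measured <- unique(attr(expr, "gene_map")[rownames(expr)])
    coll$universe <- intersect(coll$universe, measured)
    recs <- rbind(
      enrich(intersect(consensus$gene_id[consensus$direction == "up"],
                       coll$universe), coll, "up"),
      enrich(intersect(consensus$gene_id[consensus$direction == "down"],
                       coll$universe), coll, "down"))
    terms <- cluster_and_filter(recs, coll, theta = config$theta,
                                p_max = config$p_max,
                                method = config$overlap_method)
    species_res[[sp]] <- list(mask_report = report, mask = mask, expr = expr,
                              de = de, consensus = consensus,
                              clustering = clus, enrichment = recs,
                              term_clusters = terms)
  }

  crosstalk <- infer_crosstalk(species_res$human$consensus,
                               species_res$mouse$consensus,
                               data$interactions, data$orthology)

  concord <- NULL
  panel <- head(species_res$human$consensus$gene_id[
    order(pmax(species_res$human$consensus$p_1,
               species_res$human$consensus$p_2))], config$panel_size)
  if (length(panel) >= 3) {
    platform <- simulate_count_platform(count_source, panel, species = "human")
    de_counts <- de_from_counts(platform)
    de_array <- species_res$human$consensus
    de_array_df <- data.frame(gene_id = de_array$gene_id,
                              log2fc = (de_array$log2fc_1 + de_array$log2fc_2) / 2,
                              p = pmax(de_array$p_1, de_array$p_2),
                              stringsAsFactors = FALSE)
    concord <- compare_platforms(de_array_df, de_counts,
                                 alpha = config$concordance_alpha)
  }

  counts <- list(
    probes_flagged_human = sum(species_res$human$mask_report$flagged),
    probes_flagged_mouse = sum(species_res$mouse$mask_report$flagged),
    probesets_dropped_human = length(species_res$human$mask$dropped_probesets),
    probesets_dropped_mouse = length(species_res$mouse$mask$dropped_probesets),
    degs_per_line_human = vapply(species_res$human$de,
                                 function(d) sum(d$p < config$alpha), 1L),
    degs_per_line_mouse = vapply(species_res$mouse$de,
                                 function(d) sum(d$p < config$alpha), 1L),
    consensus_human = nrow(species_res$human$consensus),
    consensus_mouse = nrow(species_res$mouse$consensus),
    clustering_ari_human = if (is.null(species_res$human$clustering)) NA_real_
                           else species_res$human$clustering$ari,
    clustering_ari_mouse = if (is.null(species_res$mouse$clustering)) NA_real_
                           else species_res$mouse$clustering$ari,
    reported_terms_human = nrow(species_res$human$term_clusters$report),
    reported_terms_mouse = nrow(species_res$mouse$term_clusters$report),
    crosstalk_candidates = nrow(crosstalk),
    concordance_validated = if (is.null(concord)) NA_real_
                            else concord$validated_proportion,
    concordance_sign_agreement = if (is.null(concord)) NA_real_
                                 else concord$sign_agreement
  )
  params <- config[setdiff(names(config), c("sim", "input_dir", "out_dir"))]
  params$sim_seed <- config$sim$seed

  files <- NULL
  if (!is.null(config$out_dir))
    files <- write_run_outputs(config$out_dir, species_res, crosstalk,
                               concord, counts, params)

  structure(list(counts = counts, params = params, seed = config$sim$seed,
                 files = files,
                 wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 results = list(species = species_res, crosstalk = crosstalk,
                                concordance = concord)),
            class = "run_report")
}

write_run_outputs <- function(out_dir, species_res, crosstalk, concord,
                              counts, params) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  p <- function(...) file.path(out_dir, ...)
  written <- character(0)
  emit <- function(df, name) {
    fwrite(as.data.frame(df), p(name), sep = "\t", quote = FALSE)
    written <<- c(written, p(name))
  }
  for (sp in names(species_res)) {
    r <- species_res[[sp]]
    emit(r$mask_report, sprintf("mask_%s.tsv", sp))
    emit(data.frame(probeset_id = r$mask$dropped_probesets),
         sprintf("dropped_probesets_%s.tsv", sp))
    for (l in names(r$de)) emit(r$de[[l]], sprintf("de_%s_%s.tsv", sp, l))
    emit(r$consensus, sprintf("consensus_%s.tsv", sp))
    emit(r$enrichment, sprintf("enrichment_%s.tsv", sp))
    emit(r$term_clusters$report, sprintf("term_clusters_%s.tsv", sp))
    if (!is.null(r$clustering)) {
      nw <- p(sprintf("dendrogram_%s.nwk", sp))
      ape::write.tree(ape::as.phylo(r$clustering$hclust), file = nw)
      written <- c(written, nw)
    }
  }
  emit(crosstalk, "crosstalk_candidates.tsv")
  if (!is.null(concord)) emit(concord$per_gene, "concordance.tsv")
  report <- list(counts = counts, params = params)
  jsonlite::write_json(report, p("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(written, p("run_report.json"))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  probes flagged: %d (human) / %d (mouse)\n",
              x$counts$probes_flagged_human, x$counts$probes_flagged_mouse))
  cat(sprintf("  consensus DEGs: %d human, %d mouse\n",
              x$counts$consensus_human, x$counts$consensus_mouse))
  cat(sprintf("  clustering ARI (human/mouse): %s / %s\n",
              format(x$counts$clustering_ari_human),
              format(x$counts$clustering_ari_mouse)))
  cat(sprintf("  reported terms: %d human, %d mouse; crosstalk candidates: %d\n",
              x$counts$reported_terms_human, x$counts$reported_terms_mouse,
              x$counts$crosstalk_candidates))
  cat(sprintf("  concordance validated: %s (sign agreement %s)\n",
              format(x$counts$concordance_validated),
              format(x$counts$concordance_sign_agreement)))
  cat(sprintf("  wall time: %.1f s\n", x$wall_time_s))
  invisible(x)
}
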