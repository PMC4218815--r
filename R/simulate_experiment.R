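#' Simulate the dual-hybridization microarray experiment
#'
#' Produces probe-level log2 intensity matrices for both array species, the
#' sample sheet, and the completed planted truth. Per line and animal the
#' design contains one region-A sample (graft array), one region-C sample
#' (host array), and one region-B sample hybridized on **both** arrays; with
#' the default two lines and four animals this yields 32 array samples.
#'
#' The generative model on the raw scale is
#' `signal = mix * 2^(baseline + region_effect + probe_affinity)`, where
#' `mix` is the compartment fraction of the sample (the graft fraction `f`
#' on graft arrays in region B, `1 - f` on host arrays in region B, and 1
#' elsewhere). Probes carrying a planted implant additionally receive
#' `kappa * foreign_fraction * 2^(foreign baseline + foreign region effect)`
#' leakage in region B only. Intensities are `log2(signal)` plus iid
#' Gaussian noise of sd `noise_sd`. Planted fold changes are shared across
#' lines (region B vs A for graft genes, region B vs C for host genes).
#'
#' @param config A [sim_config()] object.
#' @param references Output of [generate_references()] for the same config.
#' @param seed Optional integer overriding the simulation RNG stream
#'   (defaults to `config$seed + 1`), so many expression replicates can be
#'   drawn from one reference set.
#' @return A list of class `xeno_sim`: `intensity_human`, `intensity_mouse`
#'   (probe x sample log2 matrices), `sample_sheet`, `probe_design`,
#'   `transcripts_human`, `transcripts_mouse`, `truth`, and `config`.
#' @examples
#' cfg <- sim_config(n_genes_per_species = 20, seed = 3)
#' sim <- simulate_experiment(cfg, generate_references(cfg))
#' dim(sim$intensity_human)
#' @export
simulate_experiment <- function(config, references, seed = NULL) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config object")
  if (!inherits(references, "xeno_references"))
    stop("references must come from generate_references()")
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)

  n <- config$n_genes_per_species
  genes_h <- names(references$transcripts_human)
  genes_m <- names(references$transcripts_mouse)

  de_h <- plant_de(genes_h, config$frac_de_human, config)
  de_m <- plant_de(genes_m, config$frac_de_mouse, config)
  base_h <- setNames(rnorm(n, 8, 1), genes_h)
  base_m <- setNames(rnorm(n, 8, 1), genes_m)

  design <- references$probe_design
  affinity <- setNames(rnorm(nrow(design), 0, 0.5), design$probe_id)

  sheet <- build_sample_sheet(config)
  b_tissues <- unique(sheet[sheet$region == "B", c("line", "animal")])
  f <- config$mixing_fraction_B
  if (config$mixing_jitter > 0) {
    f <- f + runif(nrow(b_tissues), -config$mixing_jitter, config$mixing_jitter)
    f <- pmin(pmax(f, 0.02), 0.98)
  } else {
    f <- rep(f, nrow(b_tissues))
  }
  mixing <- data.frame(b_tissues, graft_fraction = f, stringsAsFactors = FALSE)

  xhyb <- references$truth$xhyb
  int_h <- simulate_species_matrix(
    species = "human", design = design, sheet = sheet, mixing = mixing,
    base_own = base_h, fc_own = de_h$log2fc, base_for = base_m,
    fc_for = de_m$log2fc, xhyb = xhyb, affinity = affinity, config = config,
    own_region = "A")
  int_m <- simulate_species_matrix(
    species = "mouse", design = design, sheet = sheet, mixing = mixing,
    base_own = base_m, fc_own = de_m$log2fc, base_for = base_h,
    fc_for = de_h$log2fc, xhyb = xhyb, affinity = affinity, config = config,
    own_region = "C")

  truth <- list(
    de_genes_human = de_h, de_genes_mouse = de_m,
    xhyb_probe_pairs = xhyb, mixing = mixing,
    baseline_human = base_h, baseline_mouse = base_m,
    probe_affinity = affinity)

  structure(list(
    intensity_human = int_h, intensity_mouse = int_m,
    sample_sheet = sheet, probe_design = design,
    transcripts_human = references$transcripts_human,
    transcripts_mouse = references$transcripts_mouse,
    truth = truth, config = config, sim_seed = as.integer(seed)
  ), class = "xeno_sim")
}

# Planted log2 fold changes: a random subset of genes gets |log2FC| drawn
# from N(mean, sd) by rejection below the magnitude floor, random sign;
# all other genes are exactly 0.
plant_de <- function(genes, frac, config) {
  n_de <- round(frac * length(genes))
  fc <- setNames(numeric(length(genes)), genes)
  de_genes <- character(0)
  if (n_de > 0) {
    de_genes <- sample(genes, n_de)
    mag <- numeric(n_de)
    need <- seq_len(n_de)
    while (length(need)) {
      draw <- rnorm(length(need), config$de_log2fc_mean, config$de_log2fc_sd)
      keep <- draw >= config$de_log2fc_min
      mag[need[keep]] <- draw[keep]
      need <- need[!keep]
    }
    fc[de_genes] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  data.frame(gene_id = genes, log2fc = unname(fc), is_de = genes %in% de_genes,
             stringsAsFactors = FALSE)
}

build_sample_sheet <- function(config) {
  rows <- list()
  for (l in seq_len(config$n_lines)) {
    for (a in seq_len(config$n_animals_per_line)) {
      id <- sprintf("L%dM%d", l, a)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(id, c("_A_hu", "_B_hu", "_B_mo", "_C_mo")),
        line = paste0("line", l), animal = id,
        region = c("A", "B", "B", "C"),
        array_species = c("human", "human", "mouse", "mouse"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

simulate_species_matrix <- function(species, design, sheet, mixing, base_own,
                                    fc_own, base_for, fc_for, xhyb, affinity,
                                    config, own_region) {
  pd <- design[design$species == species, , drop = FALSE]
  names(fc_own) <- names(base_own)
  names(fc_for) <- names(base_for)
  base_p <- base_own[pd$gene_id] + affinity[pd$probe_id]
  fc_p <- fc_own[pd$gene_id]

  # raw-scale leakage term per implanted probe (foreign region-B abundance)
  leak <- numeric(nrow(pd))
  xh <- xhyb[xhyb$species == species, , drop = FALSE]
  if (nrow(xh)) {
    idx <- match(xh$probe_id, pd$probe_id)
    leak[idx] <- 2^(base_for[xh$foreign_gene_id] + fc_for[xh$foreign_gene_id])
  }

  cols <- sheet[sheet$array_species == species, , drop = FALSE]
  out <- matrix(NA_real_, nrow(pd), nrow(cols),
                dimnames = list(pd$probe_id, cols$sample_id))
  kappa <- config$xhyb_coupling
  for (j in seq_len(nrow(cols))) {
    if (cols$region[j] == own_region) {
      raw <- 2^(base_p)
    } else {  # region B: mixed tissue
      fg <- mixing$graft_fraction[mixing$line == cols$line[j] &
                                    mixing$animal == cols$animal[j]]
      own_frac <- if (species == "human") fg else 1 - fg
      raw <- own_frac * 2^(base_p + fc_p) + kappa * (1 - own_frac) * leak
    }
    # detection floor keeps log2 finite at extreme mixing fractions
    out[, j] <- log2(pmax(raw, 2^-10)) + rnorm(nrow(pd), 0, config$noise_sd)
  }
  out
}
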