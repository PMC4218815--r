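#' Configuration for the synthetic xenograft experiment
#'
#' Defines the study layout and generative parameters used by
#' [generate_references()] and [simulate_experiment()]. The defaults emulate
#' the laser-microdissection design the package targets: two glioma stem-cell
#' lines, four injected animals per line, and three dissected regions per
#' animal -- tumor core (A, graft species only), invasion front (B, a
#' graft/host mixture hybridized on **both** array species), and distant
#' "normal" brain (C, host species only).
#'
#' Planted differentially expressed genes change between region B and the
#' compartment's reference region (A for the graft species, C for the host
#' species), with the same effect in both lines. A fraction of probes receive
#' an implanted exact match inside a random foreign-species transcript; in
#' region B those probes leak foreign signal with coupling `xhyb_coupling`.
#'
#' @param n_genes_per_species Number of genes (one transcript each) per
#'   species.
#' @param probes_per_set Probes interrogating each transcript (tiled without
#'   overlap).
#' @param probe_length Probe length in nucleotides (>= 15).
#' @param n_lines Number of tumor lines.
#' @param n_animals_per_line Animals injected per line.
#' @param frac_de_human,frac_de_mouse Fraction of genes planted as
#'   differentially expressed in each compartment.
#' @param de_log2fc_mean,de_log2fc_sd Mean and sd of planted absolute log2
#'   fold changes (drawn by rejection so magnitudes stay >=
#'   `de_log2fc_min`); signs are random.
#' @param de_log2fc_min Minimum planted |log2FC|.
#' @param frac_xhyb_probes Fraction of probes per species that receive an
#'   implanted exact match in the foreign transcriptome.
#' @param xhyb_coupling Leakage coupling kappa in `[0, 1]`: the fraction of
#'   the foreign transcript's raw-scale abundance added to an implanted
#'   probe's signal in region B.
#' @param mixing_fraction_B Graft-species (human) fraction f of region-B
#'   tissue, in `[0, 1]`.
#' @param mixing_jitter Half-width of uniform per-sample jitter on f.
#' @param noise_sd Additive Gaussian noise sd on log2 intensities (> 0).
#' @param implant_length_min Minimum implanted exact-match length in nt;
#'   implant lengths are drawn uniformly between this and `probe_length`.
#'   This is the masking threshold the planted truth is crisp against.
#' @param seed Integer seed; identical configurations yield byte-identical
#'   simulated bundles.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes_per_species = 40, seed = 7)
#' cfg$probes_per_set
#' @export
sim_config <- function(n_genes_per_species = 600,
                       probes_per_set = 11,
                       probe_length = 25,
                       n_lines = 2,
                       n_animals_per_line = 4,
                       frac_de_human = 0.10,
                       frac_de_mouse = 0.10,
                       de_log2fc_mean = 1.5,
                       de_log2fc_sd = 0.3,
                       de_log2fc_min = 1.0,
                       frac_xhyb_probes = 0.10,
                       xhyb_coupling = 0.5,
                       mixing_fraction_B = 0.5,
                       mixing_jitter = 0,
                       noise_sd = 0.25,
                       implant_length_min = 15,
                       seed = 1L) {
  cfg <- list(
    n_genes_per_species = as.integer(n_genes_per_species),
    probes_per_set = as.integer(probes_per_set),
    probe_length = as.integer(probe_length),
    n_lines = as.integer(n_lines),
    n_animals_per_line = as.integer(n_animals_per_line),
    regions = c("A", "B", "C"),
    frac_de_human = frac_de_human,
    frac_de_mouse = frac_de_mouse,
    de_log2fc_mean = de_log2fc_mean,
    de_log2fc_sd = de_log2fc_sd,
    de_log2fc_min = de_log2fc_min,
    frac_xhyb_probes = frac_xhyb_probes,
    xhyb_coupling = xhyb_coupling,
    mixing_fraction_B = mixing_fraction_B,
    mixing_jitter = mixing_jitter,
    noise_sd = noise_sd,
    implant_length_min = as.integer(implant_length_min),
    seed = as.integer(seed),
    # derived layout constants
    flank_length = 10L,
    implant_slots_per_transcript = 2L
  )
  cfg$slot_width <- cfg$probe_length + 3L
  cfg$spacer_length <- cfg$implant_slots_per_transcript * cfg$slot_width
  cfg$transcript_length <- cfg$flank_length + cfg$probes_per_set * cfg$probe_length +
    cfg$spacer_length

  props <- c(frac_de_human = cfg$frac_de_human, frac_de_mouse = cfg$frac_de_mouse,
             frac_xhyb_probes = cfg$frac_xhyb_probes,
             xhyb_coupling = cfg$xhyb_coupling,
             mixing_fraction_B = cfg$mixing_fraction_B)
  bad_prop <- names(props)[!is.finite(props) | props < 0 | props > 1]
  n_probes <- cfg$n_genes_per_species * cfg$probes_per_set
  viol <- collect_violations(
    if (length(bad_prop))
      paste0("proportions must lie in [0, 1]: ", paste(bad_prop, collapse = ", ")),
    check_that(cfg$n_genes_per_species >= 2, "n_genes_per_species must be >= 2"),
    check_that(cfg$probes_per_set >= 1, "probes_per_set must be >= 1"),
    check_that(cfg$probe_length >= 15, "probe_length must be >= 15"),
    check_that(cfg$n_lines >= 1, "n_lines must be >= 1"),
    check_that(cfg$n_animals_per_line >= 1, "n_animals_per_line must be >= 1"),
    check_that(is.finite(cfg$noise_sd) && cfg$noise_sd > 0, "noise_sd must be > 0"),
    check_that(cfg$mixing_jitter >= 0, "mixing_jitter must be >= 0"),
    check_that(cfg$implant_length_min >= 8 &&
                 cfg$implant_length_min <= cfg$probe_length,
               "implant_length_min must lie in [8, probe_length]"),
    check_that(round(cfg$frac_xhyb_probes * n_probes) <=
                 cfg$implant_slots_per_transcript * cfg$n_genes_per_species,
               "frac_xhyb_probes too large for the available implant slots"),
    check_that(is.finite(cfg$seed), "seed must be a finite integer")
  )
  if (length(viol))
    stop("invalid simulation configuration:\n  - ",
         paste(viol, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes/species, %d probes/set of %d nt\n",
              x$n_genes_per_species, x$probes_per_set, x$probe_length))
  cat(sprintf("  %d lines x %d animals, regions A/B/C (B dual-hybridized)\n",
              x$n_lines, x$n_animals_per_line))
  cat(sprintf("  DE frac (human/mouse): %.2f/%.2f, |log2FC| >= %.2f\n",
              x$frac_de_human, x$frac_de_mouse, x$de_log2fc_min))
  cat(sprintf("  xhyb frac %.2f, coupling %.2f, mixing f = %.2f, noise sd %.2f\n",
              x$frac_xhyb_probes, x$xhyb_coupling, x$mixing_fraction_B,
              x$noise_sd))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
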