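#' Simulate a species-pure count-based validation platform
#'
#' Emulates a digital counting assay (NanoString-like) on a gene panel:
#' negative-binomial counts with mean proportional to the planted raw-scale
#' expression of each gene in its own compartment, species-pure even in the
#' mixed region (validation probes are designed without cross-species
#' hybridization, so counts carry no leakage by construction).
#' Housekeeping genes with zero planted fold change are appended for
#' size-factor normalization.
#'
#' @param sim A [simulate_experiment()] result (supplies planted baselines
#'   and fold changes).
#' @param genes Panel gene ids (subset of the simulated genes of
#'   `species`).
#' @param species `"human"` (region B vs A contrast) or `"mouse"`
#'   (B vs C).
#' @param n_housekeeping Housekeeping genes added from the non-DE pool.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param size_factor_sd Log-normal sd of per-sample library size factors.
#' @param depth Scale factor from raw expression to expected counts.
#' @param seed Integer seed for the count draws.
#' @return A list of class `count_platform`: `counts` (gene x sample),
#'   `groups` (region per sample), `housekeeping` (gene ids), `species`.
#' @export
simulate_count_platform <- function(sim, genes, species = c("human", "mouse"),
                                    n_housekeeping = 5, dispersion = 0.05,
                                    size_factor_sd = 0.2, depth = 2,
                                    seed = NULL) {
  species <- match.arg(species)
  stopifnot(inherits(sim, "xeno_sim"))
  if (is.null(seed)) seed <- sim$config$seed + 21L
  set.seed(seed)
  de <- if (species == "human") sim$truth$de_genes_human else sim$truth$de_genes_mouse
  base <- if (species == "human") sim$truth$baseline_human else sim$truth$baseline_mouse
  missing <- setdiff(genes, de$gene_id)
  if (length(missing))
    stop("panel genes absent from the simulated ", species, " genes: ",
         paste(head(missing, 5), collapse = ", "))
  hk_pool <- setdiff(de$gene_id[!de$is_de], genes)
  hk <- sample(hk_pool, min(n_housekeeping, length(hk_pool)))
  panel <- c(genes, hk)

  sheet <- sim$sample_sheet
  ref_region <- if (species == "human") "A" else "C"
  samp <- sheet[sheet$array_species == species &
                  sheet$region %in% c("B", ref_region), , drop = FALSE]
  fc <- setNames(de$log2fc, de$gene_id)[panel]
  mu0 <- depth * 2^base[panel]
  sf <- exp(rnorm(nrow(samp), 0, size_factor_sd))
  counts <- matrix(NA_real_, length(panel), nrow(samp),
                   dimnames = list(panel, samp$sample_id))
  for (j in seq_len(nrow(samp))) {
    mu <- mu0 * 2^(fc * (samp$region[j] == "B")) * sf[j]
    counts[, j] <- if (dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), lambda = mu)
  }
  structure(list(counts = counts, groups = setNames(samp$region, samp$sample_id),
                 housekeeping = hk, species = species, seed = seed),
            class = "count_platform")
}

#' Housekeeping-normalized differential expression from counts
#'
#' Normalizes each sample by the geometric mean of its housekeeping-gene
#' counts (making fold changes invariant to library scaling), then runs a
#' gene-wise Welch t-test on `log2(normalized count + 1)` for region B vs
#' the reference region -- symmetric with the array-side statistic.
#'
#' @param platform A [simulate_count_platform()] result (or any list with
#'   `counts`, `groups`, `housekeeping`).
#' @return A data.frame of class `de_result` with `gene_id`, `log2fc`,
#'   `t`, `p`, `q`, `direction` (housekeeping genes excluded from the
#'   result).
#' @export
de_from_counts <- function(platform) {
  counts <- platform$counts
  hk <- platform$housekeeping
  groups <- platform$groups[colnames(counts)]
  if (length(hk)) {
    gm <- apply(counts[hk, , drop = FALSE], 2,
                function(x) exp(mean(log(x + 1))))
    norm <- sweep(counts, 2, gm / exp(mean(log(gm))), "/")
  } else {
    norm <- counts
  }
  lx <- log2(norm + 1)
  lx <- lx[setdiff(rownames(lx), hk), , drop = FALSE]
  b <- lx[, groups == "B", drop = FALSE]
  r <- lx[, groups != "B", drop = FALSE]
  w <- welch_rows(b, r)
  out <- data.frame(feature_id = rownames(lx), gene_id = rownames(lx),
                    log2fc = w$diff, t = w$t, p = w$p,
                    q = p.adjust(w$p, method = "BH"),
                    direction = ifelse(w$diff > 0, "up",
                                       ifelse(w$diff < 0, "down", "none")),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("de_result", "data.frame"),
            line = "all", species = platform$species, contrast = "counts")
}

#' Cross-platform fold-change concordance
#'
#' Compares per-gene log2 fold changes between two differential-expression
#' results (e.g. array vs counting platform) over their shared genes:
#' per-gene sign agreement, Spearman rank correlation of log2FC, and the
#' validated proportion -- the fraction of genes significant on platform 2
#' (`p < alpha`) with the same sign as platform 1.
#'
#' @param de_platform1,de_platform2 Data frames with `gene_id`, `log2fc`,
#'   `p`.
#' @param alpha Significance threshold for "validated" calls on platform 2.
#' @return A list of class `concordance_report`: `per_gene` (gene,
#'   both log2fc, sign agreement, validated), `sign_agreement`,
#'   `spearman`, `validated_proportion`, `n_shared`, `alpha`.
#' @export
compare_platforms <- function(de_platform1, de_platform2, alpha = 0.05) {
  m <- merge(de_platform1[, c("gene_id", "log2fc", "p")],
             de_platform2[, c("gene_id", "log2fc", "p")],
             by = "gene_id", suffixes = c("_1", "_2"))
  if (!nrow(m)) stop("no shared genes between the two platforms")
  m$sign_agree <- sign(m$log2fc_1) == sign(m$log2fc_2)
  m$validated <- m$p_2 < alpha & m$sign_agree
  m <- m[order(m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(
    per_gene = m,
    sign_agreement = mean(m$sign_agree),
    spearman = cor(m$log2fc_1, m$log2fc_2, method = "spearman"),
    validated_proportion = mean(m$validated),
    n_shared = nrow(m), alpha = alpha
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d shared genes: sign agreement %.3f, Spearman %.3f, validated %.3f (alpha=%g)\n",
              x$n_shared, x$sign_agreement, x$spearman,
              x$validated_proportion, x$alpha))
  invisible(x)
}
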