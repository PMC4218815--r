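#' Per-line region contrast by gene-wise Welch t-test
#'
#' Computes, for one tumor line (or all lines pooled), the region-B-vs-
#' reference contrast for one compartment: B vs A on graft-species (human)
#' arrays, B vs C on host-species (mouse) arrays. Each feature gets a Welch
#' two-sample t on log2 expression, a two-sided p-value, and a
#' Benjamini-Hochberg adjusted q computed within the contrast. `log2fc` is
#' `mean(B) - mean(reference)`.
#'
#' Features with zero variance and identical means in both groups are
#' reported with `t = 0, p = 1` (the test is undefined there; a null call
#' is the documented convention). Zero variance with different means gives
#' `|t| = Inf, p = 0`.
#'
#' @param expr Feature x sample log2 expression matrix (e.g. from
#'   [summarize_probesets()]); columns must be sample ids present in the
#'   sample sheet.
#' @param sample_sheet Data frame with `sample_id`, `line`, `region`,
#'   `array_species`.
#' @param contrast `"B-vs-A"` (graft compartment) or `"B-vs-C"` (host
#'   compartment).
#' @param species Array species whose samples enter the contrast; region-B
#'   samples appear on both array species, so this selects the compartment.
#' @param line Optional line label; `NULL` pools all lines.
#' @return A data.frame of class `de_result`: `feature_id`, `gene_id`,
#'   `log2fc`, `t`, `p`, `q`, `direction`; metadata in attributes `line`,
#'   `species`, `contrast`.
#' @export
region_contrast <- function(expr, sample_sheet,
                            contrast = c("B-vs-A", "B-vs-C"),
                            species = c("human", "mouse"), line = NULL) {
  contrast <- match.arg(contrast)
  species <- match.arg(species)
  ref_region <- sub("B-vs-", "", contrast)

  sheet <- sample_sheet[sample_sheet$array_species == species, , drop = FALSE]
  if (!is.null(line)) sheet <- sheet[sheet$line == line, , drop = FALSE]
  grp_b <- intersect(sheet$sample_id[sheet$region == "B"], colnames(expr))
  grp_r <- intersect(sheet$sample_id[sheet$region == ref_region], colnames(expr))
  for (g in list(c("B", length(grp_b)), c(ref_region, length(grp_r))))
    if (as.integer(g[2]) < 2)
      stop(sprintf("group '%s' (%s arrays%s) has %s samples; need >= 2",
                   g[1], species,
                   if (is.null(line)) "" else paste0(", ", line), g[2]))

  w <- welch_rows(expr[, grp_b, drop = FALSE], expr[, grp_r, drop = FALSE])
  gene_map <- attr(expr, "gene_map")
  fid <- rownames(expr)
  gid <- if (!is.null(gene_map)) unname(gene_map[fid]) else fid
  gid[is.na(gid)] <- fid[is.na(gid)]
  out <- data.frame(feature_id = fid, gene_id = gid,
                    log2fc = w$diff, t = w$t, p = w$p,
                    q = p.adjust(w$p, method = "BH"),
                    direction = ifelse(w$diff > 0, "up",
                                       ifelse(w$diff < 0, "down", "none")),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("de_result", "data.frame"),
            line = if (is.null(line)) "all" else line,
            species = species, contrast = contrast,
            n_b = length(grp_b), n_ref = length(grp_r))
}

# Vectorized Welch two-sample t over matrix rows.
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) {
    same <- zero & diff == 0
    tt[same] <- 0; p[same] <- 1
    sep <- zero & diff != 0
    tt[sep] <- sign(diff[sep]) * Inf; p[sep] <- 0
  }
  list(diff = diff, t = tt, p = p)
}

#' Cross-line consensus of differential-expression results
#'
#' Genes called in **both** lines under the prioritization rule: p below
#' `alpha` in each line (raw p by default, mirroring the "significant
#' change (p < 0.05) in both xenografted lines" rule; BH-adjusted q behind
#' `use_adjusted`) and, when `require_same_direction`, an identical sign of
#' change.
#'
#' @param de_line1,de_line2 [region_contrast()] results for the same
#'   species and contrast, from different lines.
#' @param alpha Significance threshold.
#' @param require_same_direction Require matching direction in both lines.
#' @param use_adjusted Use BH-adjusted q instead of raw p.
#' @return A data.frame of class `consensus_degs` with per-line statistics;
#'   selection parameters and metadata in attributes.
#' @export
intersect_lines <- function(de_line1, de_line2, alpha = 0.05,
                            require_same_direction = TRUE,
                            use_adjusted = FALSE) {
  for (a in c("species", "contrast"))
    if (!identical(attr(de_line1, a), attr(de_line2, a)))
      stop("de results disagree on ", a, ": ",
           attr(de_line1, a), " vs ", attr(de_line2, a))
  m <- merge(as.data.frame(de_line1), as.data.frame(de_line2),
             by = c("feature_id", "gene_id"), suffixes = c("_1", "_2"))
  stat <- if (use_adjusted) cbind(m$q_1, m$q_2) else cbind(m$p_1, m$p_2)
  keep <- stat[, 1] < alpha & stat[, 2] < alpha
  if (require_same_direction)
    keep <- keep & m$direction_1 == m$direction_2 & m$direction_1 != "none"
  out <- m[keep, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out$direction <- out$direction_1
  structure(out, class = c("consensus_degs", "data.frame"),
            species = attr(de_line1, "species"),
            contrast = attr(de_line1, "contrast"),
            lines = c(attr(de_line1, "line"), attr(de_line2, "line")),
            alpha = alpha, require_same_direction = require_same_direction,
            use_adjusted = use_adjusted)
}

#' Hierarchical clustering diagnostic for region segregation
#'
#' Average-linkage hierarchical clustering of samples under correlation
#' distance (1 - Pearson), typically on the expression of consensus genes.
#' The tree is cut into two flat clusters and compared with the region
#' labels by adjusted Rand index; ARI 1 means the two regions segregate
#' perfectly, as expected when invasion-front arrays separate from their
#' reference region.
#'
#' @param expr Feature x sample matrix (restrict rows to the genes of
#'   interest first). Constant rows are dropped with a warning
#'   (correlation undefined).
#' @param region_labels Region label per column of `expr`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A list of class `sample_clustering`: `hclust`, `clusters`
#'   (2-group labels), `ari`, `region_labels`, `dropped_features`.
#' @export
cluster_samples <- function(expr, region_labels, linkage = "average") {
  if (ncol(expr) < 2 || nrow(expr) < 2)
    stop("need at least 2 samples and 2 features")
  if (length(region_labels) != ncol(expr))
    stop("region_labels must match the matrix columns")
  const <- apply(expr, 1, function(r) sd(r) == 0)
  dropped <- rownames(expr)[const]
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped before clustering")
    expr <- expr[!const, , drop = FALSE]
    if (nrow(expr) < 2) stop("fewer than 2 non-constant features remain")
  }
  d <- as.dist(1 - cor(expr))
  hc <- hclust(d, method = linkage)
  cl <- cutree(hc, k = 2)
  ari <- mclust::adjustedRandIndex(cl, region_labels)
  structure(list(hclust = hc, clusters = cl, ari = ari,
                 region_labels = region_labels, dropped_features = dropped),
            class = "sample_clustering")
}
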