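#' Quantile-normalize a probe intensity matrix
#'
#' Forces every sample column onto the identical sorted value multiset
#' (ties resolved as the mean of tied ranks), removing global per-array
#' scale differences -- including the overall signal dilution that the
#' compartment mixing fraction imposes on region-B arrays. Row order is
#' preserved. Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat Probe x sample matrix of positive (log2) intensities,
#'   at least two columns.
#' @return The normalized matrix, with a `normalization` attribute.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2)
    stop("need a matrix with at least 2 sample columns")
  if (any(!is.finite(mat)) || any(mat <= 0))
    stop("intensities must be finite and positive")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  attr(out, "normalization") <- "quantile"
  out
}

#' Median-center a probe intensity matrix across samples
#'
#' Location-only normalization: subtracts each column's median (re-adding
#' the grand median so the overall scale is preserved). Removes global
#' per-array effects -- including the uniform log2 dilution that the
#' compartment mixing fraction imposes on region-B arrays -- without
#' remapping ranks, so genes at the distribution extremes are not
#' compressed when differential expression distorts a column's tails.
#' This is the pipeline's default normalization;
#' [quantile_normalize()] is the stronger full-distribution alternative.
#'
#' @param mat Probe x sample matrix of positive (log2) intensities,
#'   at least two columns.
#' @return The normalized matrix, with a `normalization` attribute.
#' @export
scale_normalize <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2)
    stop("need a matrix with at least 2 sample columns")
  if (any(!is.finite(mat)))
    stop("intensities must be finite")
  med <- apply(mat, 2, median)
  out <- sweep(mat, 2, med - median(med))
  attr(out, "normalization") <- "median_center"
  out
}

#' Summarize probe-level intensities to probeset expression
#'
#' Collapses surviving probes of each probeset to one expression value per
#' sample: the median of member-probe log2 intensities (default; robust to
#' residual unmasked leakage) or the fitted sample effects of a Tukey
#' median polish (overall + column effect, the RMA-style summary).
#'
#' @param mat Probe x sample matrix (rownames are probe ids); typically
#'   masked and quantile-normalized.
#' @param probe_design Data frame mapping `probe_id` to `probeset_id` (and
#'   optionally `gene_id`).
#' @param method `"median"` or `"medianpolish"`.
#' @return A probeset x sample matrix of class `expression_matrix` with a
#'   `gene_map` attribute (probeset -> gene, when `gene_id` is available)
#'   and a `provenance` attribute recording the method.
#' @export
summarize_probesets <- function(mat, probe_design,
                                method = c("median", "medianpolish")) {
  method <- match.arg(method)
  ids <- rownames(mat)
  m <- match(ids, probe_design$probe_id)
  if (anyNA(m))
    stop("matrix rows missing from probe design: ",
         paste(head(ids[is.na(m)], 5), collapse = ", "))
  ps <- probe_design$probeset_id[m]

  if (method == "median") {
    dt <- as.data.table(mat)
    dt[, probeset_id := ps]
    sm <- dt[, lapply(.SD, median), by = probeset_id]
    out <- as.matrix(sm[, -1])
    rownames(out) <- sm$probeset_id
  } else {
    out <- do.call(rbind, lapply(split(seq_len(nrow(mat)), ps), function(ii) {
      block <- mat[ii, , drop = FALSE]
      if (nrow(block) == 1) return(block[1, ])
      fit <- medpolish(block, trace.iter = FALSE, maxiter = 50)
      fit$overall + fit$col
    }))
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  colnames(out) <- colnames(mat)

  gene_map <- NULL
  if ("gene_id" %in% names(probe_design)) {
    pm <- unique(probe_design[, c("probeset_id", "gene_id")])
    gene_map <- setNames(pm$gene_id, pm$probeset_id)
  }
  structure(out, class = c("expression_matrix", class(out)),
            gene_map = gene_map,
            provenance = list(summary_method = method,
                              background_correction = "none"))
}
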