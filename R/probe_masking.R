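#' Score probes for cross-hybridization against a foreign transcriptome
#'
#' For every probe, computes the longest contiguous exact match
#' (`max_contiguous_match`, in nt) shared with any foreign transcript --
#' considering both the probe and its reverse complement -- and the best
#' full-length ungapped identity over alignments anchored at shared 12-mer
#' seeds (`best_identity`; 0 when no seed is shared). A probe is `flagged`
#' when `max_contiguous_match >= l_min` or `best_identity >= i_min`.
#'
#' Matching is seed-and-extend with a 12-mer primary seed, an 8-mer second
#' pass, and an exact dynamic-programming fallback for probes whose true
#' maximum is below 8 nt, so the reported match length is exact for every
#' probe. `N` (and any non-ACGT character when `n_policy = "never_match"`)
#' never matches anything.
#'
#' @param probe_design Data frame with at least `probe_id` and `sequence`
#'   columns (e.g. from [generate_references()] or [read_fixture_bundle()]).
#' @param foreign_transcriptome Named character vector (or
#'   `Biostrings::DNAStringSet`) of foreign-species transcripts.
#' @param l_min Contiguous-match flagging threshold in nt (default 15).
#' @param i_min Identity flagging threshold over the full probe length
#'   (default 0.75). Set to 1 to require a perfect full-length match, which
#'   effectively disables the identity rule for probes shorter than their
#'   own perfect match.
#' @param seed_length Primary seed size for matching (default 12).
#' @param n_policy `"never_match"` treats non-ACGT characters as unmatchable;
#'   `"error"` rejects sequences containing them.
#' @return A data.frame of class `cross_hyb_report`: `probe_id`,
#'   `max_contiguous_match`, `best_identity`, `flagged`, with the thresholds
#'   stored as attributes.
#' @examples
#' design <- data.frame(probe_id = "p1", sequence = "ACGTACGTACGTACGTACGTACGTA")
#' score_cross_hybridization(design, c(tx = "GGGGCCCCGGGGCCCCGGGG"))
#' @export
score_cross_hybridization <- function(probe_design, foreign_transcriptome,
                                      l_min = 15, i_min = 0.75,
                                      seed_length = 12,
                                      n_policy = c("never_match", "error")) {
  n_policy <- match.arg(n_policy)
  if (!is.data.frame(probe_design) ||
      !all(c("probe_id", "sequence") %in% names(probe_design)))
    stop("probe_design must be a data.frame with probe_id and sequence columns")
  if (nrow(probe_design) == 0) stop("probe_design is empty")
  fr <- as.character(foreign_transcriptome)
  if (!length(fr)) stop("foreign transcriptome is empty")

  probes <- toupper(probe_design$sequence)
  fr <- toupper(fr)
  if (n_policy == "error") {
    bad <- grepl("[^ACGT]", probes)
    if (any(bad) || any(grepl("[^ACGT]", fr)))
      stop("non-ACGT characters present; use n_policy = \"never_match\" ",
           "or clean the input (offending probes: ",
           paste(head(probe_design$probe_id[bad], 5), collapse = ", "), ")")
  }
  # concatenate transcripts with a separator that never matches
  ref <- paste(fr, collapse = "X")
  res <- cpp_cross_hyb(probes, ref, as.integer(seed_length))
  out <- data.frame(probe_id = probe_design$probe_id,
                    max_contiguous_match = res$max_match,
                    best_identity = res$best_identity,
                    stringsAsFactors = FALSE)
  out$flagged <- out$max_contiguous_match >= l_min | out$best_identity >= i_min
  structure(out, class = c("cross_hyb_report", "data.frame"),
            l_min = l_min, i_min = i_min, seed_length = seed_length)
}

#' Build a probe mask from a cross-hybridization report
#'
#' Excludes every flagged probe, then drops entire probesets left with
#' fewer than `min_probes_per_set` surviving probes (downstream
#' summarization needs a robust location estimate).
#'
#' @param report A [score_cross_hybridization()] result covering all probes
#'   in `probe_design`.
#' @param probe_design Data frame with `probe_id` and `probeset_id`.
#' @param min_probes_per_set Minimum surviving probes per probeset.
#' @return A list of class `probe_mask`: `excluded_probes` (flagged),
#'   `dropped_probesets`, `removed_probes` (flagged plus members of dropped
#'   sets), `all_probes`, and `params`.
#' @export
build_mask <- function(report, probe_design, min_probes_per_set = 3) {
  if (!all(probe_design$probe_id %in% report$probe_id))
    stop("report does not cover all probes in the design")
  flagged <- report$probe_id[report$flagged]
  surv <- !(probe_design$probe_id %in% flagged)
  n_surv <- tapply(surv, probe_design$probeset_id, sum)
  dropped <- names(n_surv)[n_surv < min_probes_per_set]
  removed <- union(flagged,
                   probe_design$probe_id[probe_design$probeset_id %in% dropped])
  structure(list(
    excluded_probes = flagged,
    dropped_probesets = dropped,
    removed_probes = removed,
    all_probes = probe_design$probe_id,
    params = list(l_min = attr(report, "l_min"), i_min = attr(report, "i_min"),
                  min_probes_per_set = min_probes_per_set)
  ), class = "probe_mask")
}

#' @export
print.probe_mask <- function(x, ...) {
  cat(sprintf("<probe_mask> %d/%d probes excluded, %d probesets dropped (l_min=%s, i_min=%s, min_probes=%d)\n",
              length(x$excluded_probes), length(x$all_probes),
              length(x$dropped_probesets),
              format(x$params$l_min), format(x$params$i_min),
              x$params$min_probes_per_set))
  invisible(x)
}

#' Apply a probe mask to an intensity matrix
#'
#' Removes rows for excluded probes and for all members of dropped
#' probesets; sample columns are untouched. Applying a mask twice is a
#' no-op.
#'
#' @param intensity_matrix Probe x sample matrix with probe ids as rownames.
#' @param mask A [build_mask()] result.
#' @return The matrix without masked rows.
#' @export
apply_mask <- function(intensity_matrix, mask) {
  if (!inherits(mask, "probe_mask")) stop("mask must be a probe_mask object")
  ids <- rownames(intensity_matrix)
  if (is.null(ids)) stop("intensity matrix must have probe ids as rownames")
  unknown <- setdiff(ids, mask$all_probes)
  if (length(unknown))
    stop("intensity matrix contains probes unknown to the design: ",
         paste(head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) sprintf(" (+%d more)", length(unknown) - 10))
  intensity_matrix[!(ids %in% mask$removed_probes), , drop = FALSE]
}
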