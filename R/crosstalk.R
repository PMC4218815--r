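#' Normalize gene symbols across species via an orthology map
#'
#' Maps host-species (mouse) symbols into the graft-species (human)
#' namespace where a one-to-one ortholog exists; symbols without an
#' ortholog are carried through unchanged and flagged, never silently
#' matched.
#'
#' @param genes Character vector of symbols to normalize.
#' @param orthology Data frame with columns `human_symbol`, `mouse_symbol`;
#'   must be one-to-one on both columns.
#' @param from `"mouse"` (map into human namespace) or `"human"` (map into
#'   mouse namespace).
#' @return A data.frame: `gene`, `normalized`, `mapped` (logical).
#' @examples
#' m <- data.frame(human_symbol = "EFNB3", mouse_symbol = "Efnb3")
#' normalize_symbols("Efnb3", m)
#' @export
normalize_symbols <- function(genes, orthology, from = c("mouse", "human")) {
  from <- match.arg(from)
  if (!all(c("human_symbol", "mouse_symbol") %in% names(orthology)))
    stop("orthology map needs human_symbol and mouse_symbol columns")
  dup_h <- orthology$human_symbol[duplicated(orthology$human_symbol)]
  dup_m <- orthology$mouse_symbol[duplicated(orthology$mouse_symbol)]
  if (length(dup_h) || length(dup_m))
    stop("orthology map is not one-to-one; offending symbols: ",
         paste(head(unique(c(dup_h, dup_m)), 10), collapse = ", "))
  src <- if (from == "mouse") orthology$mouse_symbol else orthology$human_symbol
  dst <- if (from == "mouse") orthology$human_symbol else orthology$mouse_symbol
  idx <- match(genes, src)
  data.frame(gene = genes,
             normalized = ifelse(is.na(idx), genes, dst[idx]),
             mapped = !is.na(idx), stringsAsFactors = FALSE)
}

#' Infer inter-compartment protein-protein crosstalk candidates
#'
#' Nominates pairs (human gene, mouse gene) such that the human gene is a
#' graft-compartment consensus DEG, the mouse gene is a host-compartment
#' consensus DEG, and the unordered pair (human gene, ortholog-normalized
#' mouse gene) exists in the interaction reference. Both up- and
#' down-regulated genes are eligible; direction is reported, not filtered.
#' Pairs where the human gene equals the mouse gene's ortholog are tagged
#' homotypic. Output is deterministic (sorted).
#'
#' @param human_consensus Data frame with `gene_id` and optionally
#'   `direction` (e.g. a [intersect_lines()] result for the human
#'   compartment).
#' @param mouse_consensus Same, for the mouse compartment.
#' @param reference Data frame `gene_sym_1`, `gene_sym_2` (human-namespace
#'   unordered binding pairs) and optionally `evidence_tag`.
#' @param orthology Orthology map, see [normalize_symbols()].
#' @return A data.frame of class `crosstalk_candidates`: `human_gene`,
#'   `mouse_gene`, `mouse_gene_human_ns`, `direction_human`,
#'   `direction_mouse`, `evidence_tag`, `homotypic`.
#' @export
infer_crosstalk <- function(human_consensus, mouse_consensus, reference,
                            orthology) {
  hg <- unique(human_consensus$gene_id)
  mg <- unique(mouse_consensus$gene_id)
  dir_of <- function(df) {
    if (!"direction" %in% names(df)) return(function(g) NA_character_)
    d <- df$direction[!duplicated(df$gene_id)]
    names(d) <- df$gene_id[!duplicated(df$gene_id)]
    function(g) unname(d[g])
  }
  dh <- dir_of(human_consensus)
  dm <- dir_of(mouse_consensus)

  norm <- normalize_symbols(mg, orthology, from = "mouse")
  norm <- norm[norm$mapped, , drop = FALSE]  # unmapped genes cannot bridge
  if (!nrow(norm) || !length(hg) || !nrow(reference)) {
    out <- data.frame(human_gene = character(0), mouse_gene = character(0),
                      mouse_gene_human_ns = character(0),
                      direction_human = character(0),
                      direction_mouse = character(0),
                      evidence_tag = character(0), homotypic = logical(0),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("crosstalk_candidates", "data.frame")))
  }
  ref_key <- canonical_pair_key(reference$gene_sym_1, reference$gene_sym_2)
  ev <- if ("evidence_tag" %in% names(reference)) reference$evidence_tag
        else rep(NA_character_, nrow(reference))
  ev <- ev[!duplicated(ref_key)]
  ref_key <- ref_key[!duplicated(ref_key)]

  grid <- expand.grid(human_gene = hg, mouse_i = seq_len(nrow(norm)),
                      stringsAsFactors = FALSE)
  grid$mouse_gene <- norm$gene[grid$mouse_i]
  grid$mouse_gene_human_ns <- norm$normalized[grid$mouse_i]
  key <- canonical_pair_key(grid$human_gene, grid$mouse_gene_human_ns)
  hit <- match(key, ref_key)
  out <- grid[!is.na(hit), c("human_gene", "mouse_gene",
                             "mouse_gene_human_ns"), drop = FALSE]
  out$direction_human <- dh(out$human_gene)
  out$direction_mouse <- dm(out$mouse_gene)
  out$evidence_tag <- ev[hit[!is.na(hit)]]
  out$homotypic <- out$human_gene == out$mouse_gene_human_ns
  out <- out[order(out$human_gene, out$mouse_gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("crosstalk_candidates", "data.frame"))
}
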