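#' Generate paired species references with planted cross-hybridizing probes
#'
#' Builds a graft-species ("human-like") and a host-species ("mouse-like")
#' transcriptome plus matching probe designs. Each gene has one transcript;
#' each probeset's probes tile that transcript without overlap, so every
#' probe is an exact substring of its own transcript. A fraction
#' `frac_xhyb_probes` of probes additionally receive an implanted exact copy
#' of a probe segment (length drawn uniformly between
#' `implant_length_min` and `probe_length`) inside a dedicated spacer
#' segment of a random foreign transcript; every implant is recorded in the
#' returned truth table.
#'
#' The two species are generated over deliberately distinguishable sequence
#' spaces: graft text never contains the dinucleotides `AA` or `TT`, while
#' host text carries a `TT` anchor every 12 nt. Every 15-mer of host text
#' therefore contains a `TT` that graft probes (and their reverse
#' complements) cannot contain, so contiguous cross-species matches at or
#' above the implant length floor exist *only* where the generator planted
#' them. Each implant is additionally screened against the 15-mers of all
#' other same-species probes (both strands) and re-drawn on collision, which
#' keeps the planted cross-hybridization truth exact.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `xeno_references` with elements
#'   `transcripts_human`, `transcripts_mouse` (named character vectors),
#'   `probe_design` (data.frame: `probe_id`, `probeset_id`, `gene_id`,
#'   `species`, `start`, `sequence`) and `truth` (list with the `xhyb`
#'   implant table).
#' @examples
#' refs <- generate_references(sim_config(n_genes_per_species = 20, seed = 1))
#' head(refs$probe_design)
#' @export
generate_references <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config object")
  set.seed(config$seed)

  n <- config$n_genes_per_species
  tl <- config$transcript_length
  genes_h <- sprintf("HG%04d", seq_len(n))
  genes_m <- sprintf("MG%04d", seq_len(n))

  th <- setNames(split_text(graft_text(n * tl), n, tl), genes_h)
  tm <- setNames(split_text(host_text(n * tl), n, tl), genes_m)

  design_h <- tile_probes(th, config, species = "human")
  design_m <- tile_probes(tm, config, species = "mouse")

  imp_hm <- plant_implants(design_h, tm, config)   # human probes into mouse ref
  tm <- imp_hm$transcripts
  imp_mh <- plant_implants(design_m, th, config)   # mouse probes into human ref
  th <- imp_mh$transcripts

  xhyb <- rbind(imp_hm$xhyb, imp_mh$xhyb)
  rownames(xhyb) <- NULL

  structure(list(
    transcripts_human = th,
    transcripts_mouse = tm,
    probe_design = rbind(design_h, design_m),
    truth = list(xhyb = xhyb)
  ), class = "xeno_references")
}

# Graft-species random text: uniform over A/C/G/T with the dinucleotides AA
# and TT forbidden (fixed by iterative vectorized redraw).
graft_text <- function(len) {
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, len, replace = TRUE)
  repeat {
    bad <- which(x[-1] == x[-len] & x[-1] %in% c("A", "T")) + 1L
    if (!length(bad)) break
    x[bad] <- sample(bases, length(bad), replace = TRUE)
  }
  paste(x, collapse = "")
}

# Host-species random text: uniform A/C/G/T with a TT anchor at every
# position congruent to 1 mod 12, so every 15 nt window contains a TT.
host_text <- function(len) {
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  p <- seq(1L, len - 1L, by = 12L)
  x[p] <- "T"
  x[p + 1L] <- "T"
  paste(x, collapse = "")
}

# Cut one long generated text into equal-length transcripts (both text
# models hold under substring extraction).
split_text <- function(txt, n, tl) {
  starts <- (seq_len(n) - 1L) * tl + 1L
  substring(txt, starts, starts + tl - 1L)
}

# Non-overlapping probe tiling of each transcript, after the 5' flank.
tile_probes <- function(transcripts, config, species) {
  m <- config$probes_per_set
  pl <- config$probe_length
  starts <- config$flank_length + (seq_len(m) - 1L) * pl + 1L
  gene_ids <- rep(names(transcripts), each = m)
  st <- rep(starts, times = length(transcripts))
  data.frame(
    probe_id = paste0(gene_ids, "_p", rep(seq_len(m), length(transcripts))),
    probeset_id = paste0(gene_ids, "_at"),
    gene_id = gene_ids,
    species = species,
    start = st,
    sequence = substring(transcripts[gene_ids], st, st + pl - 1L),
    stringsAsFactors = FALSE
  )
}

# Implant exact copies of randomly chosen probe segments into spacer slots
# of foreign transcripts. Each implant is screened against the 15-mers of
# all same-species probes (both strands): if any probe other than those
# legitimately overlapping the implanted window matches, the implant is
# re-drawn, so planted truth is exact.
plant_implants <- function(src_design, target_transcripts, config) {
  empty <- data.frame(probe_id = character(0), species = character(0),
                      foreign_gene_id = character(0), foreign_pos = integer(0),
                      match_length = integer(0), stringsAsFactors = FALSE)
  n_imp <- round(config$frac_xhyb_probes * nrow(src_design))
  if (n_imp == 0)
    return(list(transcripts = target_transcripts, xhyb = empty))

  pl <- config$probe_length
  lmin <- config$implant_length_min
  spacer_start <- config$flank_length + config$probes_per_set * pl

  slots <- expand.grid(gene = seq_along(target_transcripts),
                       slot = seq_len(config$implant_slots_per_transcript))
  pick <- slots[sample(nrow(slots), n_imp), , drop = FALSE]
  src_idx <- sample(nrow(src_design), n_imp)

  # 15-mer -> probe_id lookup over both strands of all source-species probes
  k <- 15L
  seqs <- c(src_design$sequence, revcomp_chr(src_design$sequence))
  ids <- rep(src_design$probe_id, 2L)
  km_list <- lapply(seq_along(seqs), function(i) seq_kmers(seqs[i], k))
  km_dt <- data.table(kmer = unlist(km_list, use.names = FALSE),
                      id = rep(ids, lengths(km_list)))
  data.table::setkey(km_dt, kmer)

  per_transcript_src <- vector("list", length(target_transcripts))
  rec <- vector("list", n_imp)

  for (j in seq_len(n_imp)) {
    g <- pick$gene[j]
    slot <- pick$slot[j]
    probe_seq <- src_design$sequence[src_idx[j]]
    probe_id <- src_design$probe_id[src_idx[j]]
    pos0 <- spacer_start + (slot - 1L) * config$slot_width + 1L
    base_txt <- target_transcripts[[g]]
    ok <- FALSE
    for (attempt in 1:60) {
      L <- sample(seq.int(lmin, pl), 1L)
      off <- sample(pl - L + 1L, 1L)
      seg <- substr(probe_seq, off, off + L - 1L)
      cand <- base_txt
      substr(cand, pos0, pos0 + L - 1L) <- seg
      win_a <- max(1L, pos0 - (k - 1L))
      win_b <- min(nchar(cand), pos0 + L - 1L + (k - 1L))
      win_kmers <- seq_kmers(substr(cand, win_a, win_b), k)
      hits <- unique(km_dt[win_kmers, on = "kmer", nomatch = NULL]$id)
      allowed <- c(probe_id, per_transcript_src[[g]])
      if (!length(setdiff(hits, allowed))) {
        target_transcripts[[g]] <- cand
        per_transcript_src[[g]] <- c(per_transcript_src[[g]], probe_id)
        rec[[j]] <- data.frame(probe_id = probe_id,
                               species = src_design$species[src_idx[j]],
                               foreign_gene_id = names(target_transcripts)[g],
                               foreign_pos = pos0, match_length = L,
                               stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place a collision-free implant for probe ", probe_id)
  }
  list(transcripts = target_transcripts, xhyb = do.call(rbind, rec))
}
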