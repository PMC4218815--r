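#' Build synthetic gene-set collections enriched for planted DE genes
#'
#' Constructs, per species, a small GMT-style collection over the simulated
#' gene universe: two terms concentrated in planted up-regulated genes, two
#' in planted down-regulated genes (pairs share members so the
#' overlap-clustering stage has structure to find), plus background terms of
#' random membership.
#'
#' @param sim A [simulate_experiment()] result.
#' @return A list with elements `human` and `mouse`, each a list
#'   `sets` (named list term -> gene ids) and `universe`.
#' @export
build_gene_sets <- function(sim) {
  stopifnot(inherits(sim, "xeno_sim"))
  set.seed(sim$config$seed + 11L)
  list(human = species_gene_sets(sim$truth$de_genes_human),
       mouse = species_gene_sets(sim$truth$de_genes_mouse))
}

species_gene_sets <- function(de) {
  universe <- de$gene_id
  up <- de$gene_id[de$is_de & de$log2fc > 0]
  dn <- de$gene_id[de$is_de & de$log2fc < 0]
  other <- setdiff(universe, c(up, dn))
  sets <- list()
  planted_pair <- function(members, tag) {
    if (length(members) < 2) return(NULL)
    core <- sample(members, max(2, round(0.8 * length(members))))
    shared <- sample(core, max(2, round(0.6 * length(core))))
    out <- list(c(core, sample(other, min(5, length(other)))),
                c(shared, sample(other, min(8, length(other)))))
    names(out) <- paste0("T_", tag, 1:2)
    out
  }
  sets <- c(sets, planted_pair(up, "UP"), planted_pair(dn, "DN"))
  bg_size <- min(12, max(3, length(universe) %/% 10))
  bg <- lapply(1:10, function(i) sample(universe, bg_size))
  names(bg) <- sprintf("T_BG%02d", 1:10)
  list(sets = c(sets, bg), universe = universe)
}

#' Build a synthetic interaction reference with orthology map
#'
#' Produces an unordered, de-duplicated protein-binding pair table in the
#' graft-species (human) symbol namespace, a one-to-one orthology map
#' covering 90% of genes, and a bookkeeping table of "bridging" pairs
#' planted so that one side is a planted human DE gene and the other the
#' ortholog of a planted mouse DE gene.
#'
#' @param sim A [simulate_experiment()] result.
#' @param n_bridges Maximum number of planted bridging pairs.
#' @param n_background Number of random background pairs.
#' @return A list with `interactions` (`gene_sym_1`, `gene_sym_2`,
#'   `evidence_tag`), `orthology` (`human_symbol`, `mouse_symbol`) and
#'   `planted_bridges` (`human_gene`, `mouse_gene`).
#' @export
build_interaction_reference <- function(sim, n_bridges = 10, n_background = 30) {
  stopifnot(inherits(sim, "xeno_sim"))
  set.seed(sim$config$seed + 13L)
  genes_h <- sim$truth$de_genes_human$gene_id
  genes_m <- sim$truth$de_genes_mouse$gene_id
  n <- length(genes_h)
  mapped <- sort(sample(n, round(0.9 * n)))
  orthology <- data.frame(human_symbol = genes_h[mapped],
                          mouse_symbol = genes_m[mapped],
                          stringsAsFactors = FALSE)

  de_h <- sim$truth$de_genes_human$gene_id[sim$truth$de_genes_human$is_de]
  de_m <- sim$truth$de_genes_mouse$gene_id[sim$truth$de_genes_mouse$is_de]
  de_m <- de_m[de_m %in% orthology$mouse_symbol]
  nb <- min(n_bridges, length(de_h), length(de_m))
  bridges <- data.frame(human_gene = character(0), mouse_gene = character(0),
                        stringsAsFactors = FALSE)
  pairs <- data.frame(gene_sym_1 = character(0), gene_sym_2 = character(0),
                      stringsAsFactors = FALSE)
  if (nb > 0) {
    hs <- sample(de_h, nb)
    ms <- sample(de_m, nb)
    bridges <- data.frame(human_gene = hs, mouse_gene = ms,
                          stringsAsFactors = FALSE)
    ms_h <- orthology$human_symbol[match(ms, orthology$mouse_symbol)]
    pairs <- data.frame(gene_sym_1 = hs, gene_sym_2 = ms_h,
                        stringsAsFactors = FALSE)
  }
  bg <- data.frame(gene_sym_1 = sample(genes_h, n_background, replace = TRUE),
                   gene_sym_2 = sample(genes_h, n_background, replace = TRUE),
                   stringsAsFactors = FALSE)
  bg <- bg[bg$gene_sym_1 != bg$gene_sym_2, , drop = FALSE]
  all_pairs <- rbind(pairs, bg)
  key <- canonical_pair_key(all_pairs$gene_sym_1, all_pairs$gene_sym_2)
  all_pairs <- all_pairs[!duplicated(key), , drop = FALSE]
  all_pairs$evidence_tag <- "binding_db"
  rownames(all_pairs) <- NULL
  list(interactions = all_pairs, orthology = orthology,
       planted_bridges = bridges)
}

canonical_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Write a synthetic fixture bundle to disk
#'
#' Serializes a simulated experiment to plain-text formats: transcriptome
#' and probe FASTA, probe-annotation / intensity / sample-sheet / truth
#' TSVs, per-species GMT collections, and the interaction reference with
#' its orthology map. Everything round-trips bit-identically through
#' [read_fixture_bundle()].
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written file paths.
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "xeno_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  p <- function(...) file.path(dir, ...)
  tsv <- function(df, path) fwrite(df, path, sep = "\t", quote = FALSE)
  fasta <- function(x, path)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 80L)

  fasta(sim$transcripts_human, p("transcripts_human.fasta"))
  fasta(sim$transcripts_mouse, p("transcripts_mouse.fasta"))
  pd <- sim$probe_design
  for (sp in c("human", "mouse")) {
    ps <- pd[pd$species == sp, ]
    fasta(setNames(ps$sequence, ps$probe_id), p(paste0("probes_", sp, ".fasta")))
  }
  tsv(pd[, c("probe_id", "probeset_id", "gene_id", "species", "start")],
      p("probe_annotation.tsv"))
  write_intensity_tsv(sim$intensity_human, p("intensity_human.tsv"))
  write_intensity_tsv(sim$intensity_mouse, p("intensity_mouse.tsv"))
  tsv(sim$sample_sheet, p("sample_sheet.tsv"))
  tsv(sim$truth$de_genes_human, p("truth_de_human.tsv"))
  tsv(sim$truth$de_genes_mouse, p("truth_de_mouse.tsv"))
  tsv(sim$truth$xhyb_probe_pairs, p("truth_xhyb.tsv"))
  tsv(sim$truth$mixing, p("truth_mixing.tsv"))
  tsv(data.frame(
    gene_id = c(names(sim$truth$baseline_human), names(sim$truth$baseline_mouse)),
    species = rep(c("human", "mouse"),
                  c(length(sim$truth$baseline_human),
                    length(sim$truth$baseline_mouse))),
    baseline_log2 = c(unname(sim$truth$baseline_human),
                      unname(sim$truth$baseline_mouse)),
    stringsAsFactors = FALSE), p("truth_baselines.tsv"))

  gs <- build_gene_sets(sim)
  write_gmt(gs$human$sets, p("gene_sets_human.gmt"))
  write_gmt(gs$mouse$sets, p("gene_sets_mouse.gmt"))
  ref <- build_interaction_reference(sim)
  tsv(ref$interactions, p("interactions.tsv"))
  tsv(ref$orthology, p("orthology.tsv"))
  tsv(ref$planted_bridges, p("truth_bridges.tsv"))

  files <- c("transcripts_human.fasta", "transcripts_mouse.fasta",
             "probes_human.fasta", "probes_mouse.fasta",
             "probe_annotation.tsv", "intensity_human.tsv",
             "intensity_mouse.tsv", "sample_sheet.tsv", "truth_de_human.tsv",
             "truth_de_mouse.tsv", "truth_xhyb.tsv", "truth_mixing.tsv",
             "truth_baselines.tsv", "gene_sets_human.gmt",
             "gene_sets_mouse.gmt", "interactions.tsv", "orthology.tsv",
             "truth_bridges.tsv")
  invisible(setNames(file.path(dir, files), files))
}

write_intensity_tsv <- function(mat, path) {
  dt <- data.table(probe_id = rownames(mat))
  dt <- cbind(dt, as.data.table(mat))
  fwrite(dt, path, sep = "\t", quote = FALSE)
}

read_intensity_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Directory containing the bundle.
#' @return A list with intensity matrices, sample sheet, probe design (with
#'   sequences re-attached from the probe FASTA), transcriptomes, gene-set
#'   collections, interaction reference, orthology map, and truth tables.
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  rd <- function(path) setDF(fread(path, sep = "\t", header = TRUE))
  fas <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
  }
  pd <- rd(p("probe_annotation.tsv"))
  probes <- c(fas(p("probes_human.fasta")), fas(p("probes_mouse.fasta")))
  pd$sequence <- unname(probes[pd$probe_id])
  list(
    intensity_human = read_intensity_tsv(p("intensity_human.tsv")),
    intensity_mouse = read_intensity_tsv(p("intensity_mouse.tsv")),
    sample_sheet = rd(p("sample_sheet.tsv")),
    probe_design = pd,
    transcripts_human = fas(p("transcripts_human.fasta")),
    transcripts_mouse = fas(p("transcripts_mouse.fasta")),
    gene_sets_human = fgsea::gmtPathways(p("gene_sets_human.gmt")),
    gene_sets_mouse = fgsea::gmtPathways(p("gene_sets_mouse.gmt")),
    interactions = rd(p("interactions.tsv")),
    orthology = rd(p("orthology.tsv")),
    truth = list(
      de_genes_human = rd(p("truth_de_human.tsv")),
      de_genes_mouse = rd(p("truth_de_mouse.tsv")),
      xhyb_probe_pairs = rd(p("truth_xhyb.tsv")),
      mixing = rd(p("truth_mixing.tsv")),
      baselines = rd(p("truth_baselines.tsv")),
      bridges = rd(p("truth_bridges.tsv"))
    )
  )
}
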