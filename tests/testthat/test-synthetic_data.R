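test_that("generator honors the requested layout and implant bookkeeping", {
  cfg <- sim_config(n_genes_per_species = 30, probes_per_set = 5, seed = 11)
  refs <- generate_references(cfg)
  sim <- simulate_experiment(cfg, refs)

  # 2 lines x 4 animals x (A + C + B on both arrays) = 32 array samples
  expect_equal(nrow(sim$sample_sheet), 32)
  expect_equal(sum(sim$sample_sheet$region == "B"), 16)
  per_animal <- table(sim$sample_sheet$animal)
  expect_true(all(per_animal == 4))
  expect_equal(ncol(sim$intensity_human), 16)
  expect_equal(ncol(sim$intensity_mouse), 16)

  # every probe is an exact substring of its own transcript
  pd <- sim$probe_design
  own <- c(sim$transcripts_human, sim$transcripts_mouse)[pd$gene_id]
  expect_true(all(mapply(grepl, pd$sequence, own, fixed = TRUE)))

  # implant count equals round(frac * n_probes), per species
  n_probes <- cfg$n_genes_per_species * cfg$probes_per_set
  xh <- sim$truth$xhyb_probe_pairs
  expect_equal(sum(xh$species == "human"), round(cfg$frac_xhyb_probes * n_probes))
  expect_equal(sum(xh$species == "mouse"), round(cfg$frac_xhyb_probes * n_probes))
  expect_true(all(xh$match_length >= cfg$implant_length_min))
})

test_that("planted implants are verified by a brute-force substring oracle", {
  cfg <- sim_config(n_genes_per_species = 25, probes_per_set = 4,
                    frac_xhyb_probes = 0.1, seed = 21)
  refs <- generate_references(cfg)
  pd <- refs$probe_design
  truth <- refs$truth$xhyb

  for (sp in c("human", "mouse")) {
    foreign <- if (sp == "human") refs$transcripts_mouse else refs$transcripts_human
    probes <- pd[pd$species == sp, ]
    oracle_max <- vapply(probes$sequence, lcs_oracle, 1L,
                         transcripts = foreign, USE.NAMES = FALSE)
    oracle_hits <- probes$probe_id[oracle_max >= cfg$implant_length_min]
    expect_setequal(oracle_hits, truth$probe_id[truth$species == sp])
  }
})

test_that("no implants are planted when frac_xhyb_probes is zero", {
  cfg <- sim_config(n_genes_per_species = 15, probes_per_set = 3,
                    frac_xhyb_probes = 0, seed = 2)
  refs <- generate_references(cfg)
  expect_equal(nrow(refs$truth$xhyb), 0)
})

test_that("identical seeds yield identical simulations and bundles", {
  cfg <- sim_config(n_genes_per_species = 15, probes_per_set = 3, seed = 5)
  sim1 <- simulate_experiment(cfg, generate_references(cfg))
  sim2 <- simulate_experiment(cfg, generate_references(cfg))
  expect_identical(sim1$intensity_human, sim2$intensity_human)
  expect_identical(sim1$truth, sim2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_fixture_bundle(sim1, d1)
  f2 <- write_fixture_bundle(sim2, d2)
  expect_identical(names(f1), names(f2))
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = paste("file", nm))
})

test_that("noiseless unmixed limit recovers planted fold changes exactly", {
  cfg <- sim_config(n_genes_per_species = 20, probes_per_set = 4,
                    noise_sd = 1e-9, mixing_fraction_B = 1,
                    xhyb_coupling = 0, seed = 8)
  sim <- simulate_experiment(cfg, generate_references(cfg))
  sheet <- sim$sample_sheet
  b_cols <- sheet$sample_id[sheet$array_species == "human" & sheet$region == "B"]
  a_cols <- sheet$sample_id[sheet$array_species == "human" & sheet$region == "A"]
  pd <- sim$probe_design[sim$probe_design$species == "human", ]
  diff_probe <- rowMeans(sim$intensity_human[, b_cols]) -
    rowMeans(sim$intensity_human[, a_cols])
  est <- tapply(diff_probe, pd$gene_id, mean)
  fc <- setNames(sim$truth$de_genes_human$log2fc, sim$truth$de_genes_human$gene_id)
  expect_equal(as.numeric(est[names(fc)]), unname(fc), tolerance = 1e-6)
})

test_that("leakage is local to implanted probes and vanishes at zero coupling", {
  cfg <- sim_config(n_genes_per_species = 40, probes_per_set = 5,
                    xhyb_coupling = 0.8, noise_sd = 0.05, seed = 13)
  sim <- simulate_experiment(cfg, generate_references(cfg))
  sheet <- sim$sample_sheet
  b_cols <- sheet$sample_id[sheet$array_species == "mouse" & sheet$region == "B"]
  pd <- sim$probe_design[sim$probe_design$species == "mouse", ]
  tr <- sim$truth
  f <- tr$mixing$graft_fraction[1]
  # expected leak-free region-B log2 signal per mouse probe
  fc <- setNames(tr$de_genes_mouse$log2fc, tr$de_genes_mouse$gene_id)
  clean <- log2((1 - f)) + tr$baseline_mouse[pd$gene_id] + fc[pd$gene_id] +
    tr$probe_affinity[pd$probe_id]
  resid <- rowMeans(sim$intensity_mouse[, b_cols]) - clean
  implanted <- pd$probe_id %in% tr$xhyb_probe_pairs$probe_id
  expect_gt(mean(resid[implanted]), 0.2)
  expect_lt(abs(mean(resid[!implanted])), 0.05)

  # planted foreign abundance drives the excess, probe by probe
  xh <- tr$xhyb_probe_pairs[tr$xhyb_probe_pairs$species == "mouse", ]
  foreign_raw <- 2^(tr$baseline_human[xh$foreign_gene_id] +
                      setNames(tr$de_genes_human$log2fc,
                               tr$de_genes_human$gene_id)[xh$foreign_gene_id])
  excess <- resid[match(xh$probe_id, pd$probe_id)]
  expected_excess <- log2(1 + 0.8 * f * foreign_raw /
                            2^(clean[match(xh$probe_id, pd$probe_id)]))
  expect_gt(cor(excess, expected_excess), 0.95)

  # zero coupling: implanted probes behave like unimplanted ones
  cfg0 <- sim_config(n_genes_per_species = 40, probes_per_set = 5,
                     xhyb_coupling = 0, noise_sd = 0.05, seed = 13)
  sim0 <- simulate_experiment(cfg0, generate_references(cfg0))
  resid0 <- rowMeans(sim0$intensity_mouse[, b_cols]) - clean
  expect_lt(abs(mean(resid0[implanted]) - mean(resid0[!implanted])), 0.03)
})

test_that("fixture bundles round-trip and keep referential integrity", {
  sim <- small_sim(seed = 31)
  dir <- withr::local_tempdir()
  write_fixture_bundle(sim, dir)
  b <- read_fixture_bundle(dir)

  expect_equal(b$intensity_human, sim$intensity_human)
  expect_equal(b$intensity_mouse, sim$intensity_mouse)
  expect_equal(b$sample_sheet, sim$sample_sheet, ignore_attr = TRUE)
  expect_equal(b$probe_design$sequence, sim$probe_design$sequence)
  expect_identical(b$transcripts_human, sim$transcripts_human)

  # every GMT member exists in the annotation universe
  genes_h <- unique(sim$probe_design$gene_id[sim$probe_design$species == "human"])
  expect_true(all(unlist(b$gene_sets_human) %in% genes_h))

  # at least one planted bridging pair is present in the interaction TSV
  expect_gt(nrow(b$truth$bridges), 0)
  orth <- b$orthology
  bridge_h <- b$truth$bridges$human_gene[1]
  bridge_m_h <- orth$human_symbol[match(b$truth$bridges$mouse_gene[1],
                                        orth$mouse_symbol)]
  keys <- paste(pmin(b$interactions$gene_sym_1, b$interactions$gene_sym_2),
                pmax(b$interactions$gene_sym_1, b$interactions$gene_sym_2))
  expect_true(paste(min(bridge_h, bridge_m_h), max(bridge_h, bridge_m_h)) %in% keys)
})
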