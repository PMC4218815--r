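test_that("verbatim foreign probes are flagged and clean probes are not", {
  set.seed(1)
  tx <- c(t1 = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                     collapse = ""))
  verbatim <- substr(tx[[1]], 50, 74)
  clean <- paste(rep("CG", 13), collapse = "")  # shares no 8-mer with poly-A
  design <- data.frame(probe_id = c("hit", "rc_hit", "clean"),
                       sequence = c(verbatim, revcomp_oracle(verbatim), clean),
                       stringsAsFactors = FALSE)
  rep1 <- score_cross_hybridization(design, tx, l_min = 15, i_min = 0.75)
  expect_equal(rep1$max_contiguous_match[1], 25)
  expect_true(rep1$flagged[1])
  expect_true(rep1$flagged[2])  # reverse complement counts

  rep2 <- score_cross_hybridization(
    data.frame(probe_id = "p", sequence = clean),
    c(t1 = strrep("A", 500)), l_min = 15, i_min = 0.75)
  expect_false(rep2$flagged[1])
  expect_equal(rep2$best_identity[1], 0)
})

test_that("seed-and-extend matcher equals the DP oracle, including N handling", {
  set.seed(42)
  tx <- c(t1 = paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                     collapse = ""),
          t2 = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                     collapse = ""))
  probes <- vapply(1:60, function(i) random_probe(25), character(1))
  # plant matches of assorted lengths, some below the seed sizes
  for (i in 1:20) {
    L <- sample(3:25, 1)
    start <- sample(1500, 1)
    seg <- substr(tx[[1 + i %% 2]], start, start + L - 1)
    off <- sample(25 - L + 1, 1)
    substr(probes[i], off, off + L - 1) <- seg
  }
  probes[61] <- paste0(substr(probes[1], 1, 20), "NNNNN")  # N never matches
  design <- data.frame(probe_id = paste0("p", seq_along(probes)),
                       sequence = probes, stringsAsFactors = FALSE)
  rep <- score_cross_hybridization(design, tx)
  oracle <- vapply(probes, lcs_oracle, 1L, transcripts = tx, USE.NAMES = FALSE)
  expect_equal(rep$max_contiguous_match, oracle)
})

test_that("flagging is monotone in the contiguous-match threshold", {
  sim <- small_sim(seed = 3)
  design <- sim$probe_design[sim$probe_design$species == "human", ]
  r_strict <- score_cross_hybridization(design, sim$transcripts_mouse,
                                        l_min = 18, i_min = 1)
  r_loose <- score_cross_hybridization(design, sim$transcripts_mouse,
                                       l_min = 12, i_min = 1)
  expect_identical(r_strict$max_contiguous_match, r_loose$max_contiguous_match)
  expect_true(all(r_loose$flagged[r_strict$flagged]))  # lowering l_min never unflags
  expect_gte(sum(r_loose$flagged), sum(r_strict$flagged))
})

test_that("mask excludes planted probes exactly on synthetic data", {
  sim <- small_sim(seed = 9)
  truth <- sim$truth$xhyb_probe_pairs
  for (sp in c("human", "mouse")) {
    design <- sim$probe_design[sim$probe_design$species == sp, ]
    foreign <- if (sp == "human") sim$transcripts_mouse else sim$transcripts_human
    rep <- score_cross_hybridization(design, foreign,
                                     l_min = sim$config$implant_length_min,
                                     i_min = 1)
    mask <- build_mask(rep, design)
    expect_setequal(mask$excluded_probes, truth$probe_id[truth$species == sp])
  }
})

test_that("probesets with too few survivors are dropped wholesale", {
  design <- data.frame(probe_id = paste0("p", 1:14),
                       probeset_id = rep(c("ps1", "ps2"), c(11, 3)),
                       sequence = "ACGT", stringsAsFactors = FALSE)
  rep <- data.frame(probe_id = design$probe_id,
                    max_contiguous_match = c(rep(25, 10), 0, 0, 0, 0),
                    best_identity = 0,
                    flagged = c(rep(TRUE, 10), rep(FALSE, 4)))
  mask <- build_mask(rep, design, min_probes_per_set = 3)
  expect_equal(mask$dropped_probesets, "ps1")
  expect_setequal(mask$removed_probes, paste0("p", 1:11))

  none <- rep; none$flagged <- FALSE
  mask0 <- build_mask(none, design, min_probes_per_set = 3)
  expect_length(mask0$excluded_probes, 0)
  expect_length(mask0$dropped_probesets, 0)
})

test_that("apply_mask removes exactly the masked rows and is idempotent", {
  design <- data.frame(probe_id = paste0("p", 1:9),
                       probeset_id = rep(c("a", "b", "c"), each = 3),
                       sequence = "ACGT", stringsAsFactors = FALSE)
  m <- matrix(rnorm(18), 9, 2, dimnames = list(design$probe_id, c("s1", "s2")))
  rep <- data.frame(probe_id = design$probe_id,
                    max_contiguous_match = 0, best_identity = 0,
                    flagged = design$probe_id %in% c("p1", "p4"))
  mask <- build_mask(rep, design, min_probes_per_set = 3)  # a and b dropped
  out <- apply_mask(m, mask)
  expect_equal(rownames(out), paste0("p", 7:9))
  expect_identical(apply_mask(out, mask), out)

  empty_rep <- rep; empty_rep$flagged <- FALSE
  empty_mask <- build_mask(empty_rep, design, min_probes_per_set = 1)
  expect_identical(apply_mask(m, empty_mask), m)

  rownames(m)[1] <- "stranger"
  expect_error(apply_mask(m, mask), "stranger")
})

test_that("non-ACGT input is rejected under the strict policy", {
  design <- data.frame(probe_id = "p1", sequence = "ACGTNACGTNACGTNACGTNACGTN")
  expect_error(
    score_cross_hybridization(design, c(t = strrep("ACGT", 20)),
                              n_policy = "error"),
    "non-ACGT")
})
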