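test_that("hypergeometric tail matches closed forms", {
  universe <- paste0("g", 1:20)
  coll <- list(sets = list(term = universe[1:5]), universe = universe)
  res <- enrich(universe[1:5], coll, "up")
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)

  # saturated list: every term fully drawn, p = 1
  coll2 <- list(sets = list(a = universe[1:5], b = universe[3:12]),
                universe = universe)
  sat <- enrich(universe, coll2, "up")
  expect_true(all(sat$k == sat$K))
  expect_true(all(sat$p == 1))

  expect_error(enrich(c("g1", "nope"), coll, "up"), "nope")
})

test_that("a term loaded with list genes ranks first", {
  set.seed(2)
  universe <- paste0("g", 1:200)
  hits <- paste0("g", 1:20)
  planted <- c(sample(hits, 16), sample(setdiff(universe, hits), 4))
  coll <- list(sets = c(list(planted = planted),
                        setNames(lapply(1:8, function(i) sample(universe, 20)),
                                 paste0("bg", 1:8))),
               universe = universe)
  res <- enrich(hits, coll, "up")
  expect_equal(res$term_id[1], "planted")
})

test_that("overlap coefficient matches its definition", {
  A <- paste0("g", 1:10)
  B <- paste0("g", 6:25)
  expect_equal(overlap_coefficient(A, B), 0.5)  # 5 shared / min(10, 20)
  expect_equal(overlap_coefficient(A, A), 1)
  expect_equal(overlap_coefficient(A, paste0("x", 1:4)), 0)
  expect_equal(overlap_coefficient(A, B), overlap_coefficient(B, A))
  expect_equal(overlap_coefficient(A[1:3], A), 1)  # containment
  expect_equal(overlap_coefficient(A, B, method = "jaccard"), 5 / 25)
  expect_error(overlap_coefficient(character(0), A), "empty")
})

test_that("overlap filtering reports only terms with a >= theta partner", {
  universe <- paste0("g", 1:100)
  sets <- list(a = universe[1:10], b = universe[6:15], c = universe[11:20],
               lone = universe[50:60])
  coll <- list(sets = sets, universe = universe)
  recs <- data.frame(term_id = names(sets), direction = "up", k = 3, n = 10,
                     K = 10, N = 100, p = c(0.01, 0.02, 0.03, 0.001),
                     overlap_genes = "", q = 0.1, stringsAsFactors = FALSE)
  tc <- cluster_and_filter(recs, coll, theta = 0.30)
  expect_setequal(tc$report$term_id, c("a", "b", "c"))
  expect_equal(tc$singletons$term_id, "lone")
  expect_length(tc$clusters, 1)
  expect_setequal(tc$clusters[[1]], c("a", "b", "c"))

  # two disjoint significant terms: both excluded from the report
  coll2 <- list(sets = list(a = universe[1:10], b = universe[30:40]),
                universe = universe)
  recs2 <- recs[1:2, ]
  tc2 <- cluster_and_filter(recs2, coll2, theta = 0.30)
  expect_equal(nrow(tc2$report), 0)
  expect_equal(nrow(tc2$singletons), 2)
})

test_that("overlap clustering equals a union-find oracle on random instances", {
  set.seed(8)
  universe <- paste0("g", 1:120)
  for (rep_i in 1:3) {
    sets <- lapply(1:30, function(i) sample(universe, sample(5:25, 1)))
    names(sets) <- sprintf("t%02d", 1:30)
    coll <- list(sets = sets, universe = universe)
    recs <- data.frame(term_id = names(sets), direction = "up", k = 1,
                       n = 10, K = lengths(sets), N = 120, p = 0.01,
                       overlap_genes = "", q = 0.1, stringsAsFactors = FALSE)
    tc <- cluster_and_filter(recs, coll, theta = 0.30)
    oracle <- overlap_cluster_oracle(sets, theta = 0.30)

    expect_setequal(tc$report$term_id, names(sets)[oracle$has_partner])
    # identical partitions: compare co-membership over reported terms
    for (cl in tc$clusters) {
      idx <- match(cl, names(sets))
      expect_length(unique(oracle$membership[idx]), 1)
    }
    n_oracle_clusters <- length(unique(
      oracle$membership[oracle$has_partner]))
    expect_length(tc$clusters, n_oracle_clusters)
  }
})

test_that("raising theta never grows a cluster", {
  set.seed(12)
  universe <- paste0("g", 1:80)
  sets <- lapply(1:15, function(i) sample(universe, sample(5:20, 1)))
  names(sets) <- paste0("t", 1:15)
  coll <- list(sets = sets, universe = universe)
  recs <- data.frame(term_id = names(sets), direction = "up", k = 1, n = 10,
                     K = lengths(sets), N = 80, p = 0.01, overlap_genes = "",
                     q = 0.1, stringsAsFactors = FALSE)
  lo <- cluster_and_filter(recs, coll, theta = 0.25)
  hi <- cluster_and_filter(recs, coll, theta = 0.45)
  # every high-theta cluster is contained in some low-theta cluster
  for (cl in hi$clusters) {
    containing <- vapply(lo$clusters, function(x) all(cl %in% x), logical(1))
    expect_true(any(containing))
  }
  expect_lte(nrow(hi$report), nrow(lo$report))
})
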