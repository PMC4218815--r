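make_expr <- function(values, sheet) {
  matrix(values, nrow = 1, dimnames = list("g1", sheet$sample_id))
}

toy_sheet <- function(n_per_group = 4) {
  data.frame(
    sample_id = paste0("s", seq_len(2 * n_per_group)),
    line = "line1", animal = paste0("m", seq_len(2 * n_per_group)),
    region = rep(c("B", "A"), each = n_per_group),
    array_species = "human", stringsAsFactors = FALSE)
}

test_that("degenerate and separated genes get the documented calls", {
  sheet <- toy_sheet()
  de_null <- region_contrast(make_expr(rep(5, 8), sheet), sheet,
                             "B-vs-A", "human")
  expect_equal(de_null$log2fc, 0)
  expect_equal(de_null$p, 1)
  expect_equal(de_null$direction, "none")

  set.seed(7)
  vals <- c(rep(1, 4), rep(0, 4)) + rnorm(8, 0, 1e-6)
  de_sep <- region_contrast(make_expr(vals, sheet), sheet, "B-vs-A", "human")
  expect_equal(de_sep$log2fc, 1, tolerance = 1e-4)
  expect_lt(de_sep$p, 1e-10)
  expect_equal(de_sep$direction, "up")
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  sheet <- toy_sheet()
  set.seed(11)
  expr <- matrix(rnorm(80), 10, 8,
                 dimnames = list(paste0("g", 1:10), sheet$sample_id))
  de1 <- region_contrast(expr, sheet, "B-vs-A", "human")
  swapped <- sheet
  swapped$region <- ifelse(sheet$region == "B", "A", "B")
  de2 <- region_contrast(expr, swapped, "B-vs-A", "human")
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$p, de2$p)
})

test_that("BH adjustment is monotone in p rank and bounded", {
  sheet <- toy_sheet()
  set.seed(3)
  expr <- matrix(rnorm(400), 50, 8,
                 dimnames = list(paste0("g", 1:50), sheet$sample_id))
  de <- region_contrast(expr, sheet, "B-vs-A", "human")
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= -1e-15))
  expect_true(all(de$q >= de$p - 1e-15))
  expect_true(all(de$q >= 0 & de$q <= 1))
  expect_equal(de$q, p.adjust(de$p, "BH"))
})

test_that("groups below two samples raise an error naming the group", {
  sheet <- toy_sheet()
  sheet <- sheet[-(1:3), ]  # one region-B sample left
  expr <- matrix(rnorm(5), 1, 5, dimnames = list("g1", sheet$sample_id))
  expect_error(region_contrast(expr, sheet, "B-vs-A", "human"), "'B'")
})

test_that("cross-line intersection follows the significance and direction rule", {
  base <- data.frame(feature_id = paste0("f", 1:4),
                     gene_id = paste0("g", 1:4),
                     log2fc = c(2, 2, -1, 0.5), t = 1,
                     p = c(0.01, 0.2, 0.01, 0.01), q = 0.5,
                     direction = c("up", "up", "down", "up"),
                     stringsAsFactors = FALSE)
  mk <- function(df, line) structure(df, class = c("de_result", "data.frame"),
                                     line = line, species = "human",
                                     contrast = "B-vs-A")
  other <- base
  other$p <- c(0.02, 0.01, 0.03, 0.04)
  other$log2fc <- c(1, 1, 2, 1)
  other$direction <- c("up", "up", "up", "up")
  cons <- intersect_lines(mk(base, "line1"), mk(other, "line2"))
  # g2 fails p in line1, g3 flips direction, g1/g4 pass
  expect_setequal(cons$gene_id, c("g1", "g4"))
  expect_lte(nrow(cons), min(sum(base$p < 0.05), sum(other$p < 0.05)))

  no_dir <- intersect_lines(mk(base, "line1"), mk(other, "line2"),
                            require_same_direction = FALSE)
  expect_setequal(no_dir$gene_id, c("g1", "g3", "g4"))

  disjoint <- other
  disjoint$p <- c(0.9, 0.9, 0.9, 0.9)
  expect_equal(nrow(intersect_lines(mk(base, "line1"), mk(disjoint, "line2"))), 0)

  wrong <- mk(other, "line2")
  attr(wrong, "contrast") <- "B-vs-C"
  expect_error(intersect_lines(mk(base, "line1"), wrong), "contrast")
})

test_that("clustering diagnostic separates built-in blocks and rejects noise", {
  set.seed(5)
  mu_a <- rnorm(10, 0, 2)
  mu_b <- mu_a + c(rep(3, 5), rep(-3, 5))  # half up, half down in group B
  block <- cbind(matrix(mu_a, 10, 4) + rnorm(40, 0, 0.1),
                 matrix(mu_b, 10, 4) + rnorm(40, 0, 0.1))
  rownames(block) <- paste0("g", 1:10)
  colnames(block) <- paste0("s", 1:8)
  labels <- rep(c("A", "B"), each = 4)
  res <- cluster_samples(block, labels)
  expect_equal(res$ari, 1)

  perm <- sample(labels)
  res_perm <- cluster_samples(block, perm)
  expect_lt(abs(res_perm$ari), 0.6)

  with_const <- rbind(block, gx = rep(1, 8))
  expect_warning(res2 <- cluster_samples(with_const, labels), "constant")
  expect_equal(res2$ari, 1)
})
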