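test_that("delta-expression is alternative minus common", {
  e <- tibble::tibble(expr_common = c(3, 2, 4), expr_alt = c(5, 2, 1))
  expect_equal(delta_expression(e)$delta_expr, c(2, 0, -3))
  bad <- tibble::tibble(expr_common = NA_real_, expr_alt = 1)
  expect_error(delta_expression(bad), class = "cisomr_validation_error")
})

test_that("perfect monotone vectors give rho of +/-1 with the smallest exact p", {
  res <- spearman_test(1:6, c(10, 20, 30, 40, 50, 60))
  expect_equal(res$estimate, 1)
  expect_equal(res$method, "exact_permutation")
  # only the identity and the full reversal reach |rho| = 1 among 720
  expect_equal(res$p.value, 2 / factorial(6))
  dec <- spearman_test(1:6, 6:1)
  expect_equal(dec$estimate, -1)
  expect_equal(dec$p.value, 2 / factorial(6))
})

test_that("exact p equals brute-force enumeration over all permutations", {
  set.seed(61)
  for (n in 4:6) {
    for (rep in 1:3) {
      x <- rnorm(n)
      y <- rnorm(n)
      res <- spearman_test(x, y)
      expect_equal(res$method, "exact_permutation")
      expect_equal(res$p.value, oracle_spearman_p(x, y), tolerance = 1e-12)
      # rho agrees with the standard estimator
      expect_equal(res$estimate, cor(x, y, method = "spearman"),
                   tolerance = 1e-12)
    }
  }
  # ties handled by average ranks in both routes
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 4, 4, 6, 5)
  expect_equal(spearman_test(x, y)$p.value, oracle_spearman_p(x, y),
               tolerance = 1e-12)
})

test_that("large samples switch to the t approximation and match cor.test", {
  set.seed(62)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  res <- spearman_test(x, y)
  expect_equal(res$method, "t_approximation")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(res$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p.value, ct$p.value, tolerance = 1e-9)
})

test_that("spearman is symmetric and invariant to monotone transforms", {
  set.seed(63)
  x <- rnorm(8); y <- rnorm(8)
  a <- spearman_test(x, y); b <- spearman_test(y, x)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$p.value, b$p.value)
  m <- spearman_test(exp(x), y^3 + 10 * y)
  expect_equal(m$estimate, a$estimate, tolerance = 1e-12)
  expect_equal(m$p.value, a$p.value, tolerance = 1e-12)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(spearman_test(rep(1, 5), 1:5), class = "cisomr_degenerate_input")
  expect_error(spearman_test(1:2, 1:2), class = "cisomr_insufficient_data")
  expect_error(spearman_test(1:4, 1:5), "equal length")
  expect_error(spearman_test(c(1, 2, NA, 4), 1:4),
               class = "cisomr_validation_error")
})

test_that("correlate_deltas joins, deduplicates and reports diagnostics", {
  d <- tibble::tibble(id = c("v1", "v2", "v3", "v3", "v4"),
                      tf = "P53",
                      delta = c(-3, 0, 2, 5, -1))
  e <- tibble::tibble(variant_id = c("v1", "v2", "v3", "v4"),
                      expr_common = 10,
                      expr_alt = 10 + 2 * c(-3, 0, 5, -1))
  res <- correlate_deltas(d, e, tf = "P53")
  expect_equal(res$n, 4)  # v3 deduplicated to its max-|delta| record
  expect_equal(res$estimate, 1)
  expect_equal(res$data$delta[res$data$id == "v3"], 5)
  # dropping zero-delta pairs only changes n
  nz <- correlate_deltas(d, e, tf = "P53", include_zero_delta = FALSE)
  expect_equal(nz$n, 3)
  expect_equal(nz$estimate, 1)
  # no joinable ids
  e2 <- e |> dplyr::mutate(variant_id = paste0("x", variant_id))
  err <- tryCatch(correlate_deltas(d, e2), error = function(e) e)
  expect_s3_class(err, "cisomr_insufficient_data")
  expect_match(conditionMessage(err), "0 joinable")
})

test_that("a noiseless linear binding-expression link yields rho = 1", {
  set.seed(64)
  d <- tibble::tibble(id = paste0("v", 1:12), tf = "cMYC",
                      delta = rnorm(12))
  e <- simulate_expression(d, slope = 2, noise_sd = 0, seed = 9)
  expect_equal(delta_expression(e)$delta_expr, 2 * d$delta, tolerance = 1e-12)
  res <- correlate_deltas(d, e, tf = "cMYC")
  expect_equal(res$estimate, 1)
})

test_that("tidy, glance, print and autoplot expose the fitted correlation", {
  res <- spearman_test(1:8, c(2, 1, 3, 5, 4, 6, 8, 7))
  td <- tidy(res)
  expect_named(td, c("estimate", "p.value", "method", "alternative", "tf"))
  gl <- glance(res)
  expect_equal(gl$n, 8)
  expect_output(print(res), "rho")
  d <- tibble::tibble(id = paste0("v", 1:10), tf = "P53", delta = rnorm(10))
  e <- simulate_expression(d, slope = 1, noise_sd = 0.1, seed = 2)
  full <- correlate_deltas(d, e)
  pl <- ggplot2::autoplot(full)
  expect_s3_class(pl, "ggplot")
  expect_error(ggplot2::autoplot(res), "no paired data")
})

test_that("burden summaries count by gene and chromosome", {
  expect_equal(nrow(burden_summary(tibble::tibble(chrom = character()))), 0)
  v <- tibble::tibble(
    chrom = c(rep("chr1", 30), rep("chr2", 5)),
    gene = c(rep("geneA", 30), rep("geneB", 5)))
  b <- burden_summary(v)
  expect_equal(b$n_variants[b$group == "gene" & b$name == "geneA"], 30L)
  expect_equal(b$n_variants[b$group == "gene" & b$name == "geneB"], 5L)
  set.seed(65)
  v2 <- tibble::tibble(chrom = sample(paste0("chr", 1:4), 200, replace = TRUE),
                       gene = sample(letters[1:6], 200, replace = TRUE))
  b2 <- burden_summary(v2)
  tab <- table(v2$chrom)
  for (ch in names(tab)) {
    expect_equal(b2$n_variants[b2$group == "chromosome" & b2$name == ch],
                 unname(unclass(tab[ch])))
  }
  # sorted descending within groups
  expect_false(is.unsorted(rev(b2$n_variants[b2$group == "gene"])))
  pl <- plot_burden(b2)
  expect_s3_class(pl, "ggplot")
})

test_that("GTEx-style long tables reshape to one row per variant", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    variant_id = rep(c("rs1", "rs2"), each = 6),
    gene = rep(c("g1", "g2"), each = 6),
    genotype_class = rep(c("common_hom", "het", "alt_hom"), 4),
    median_expression = c(10, 12, 14, 10, 12, 14, 5, 4, 3, 7, 6, 8),
    tissue = rep(c("blood", "blood", "blood", "skin", "skin", "skin"), 2)), f)
  e <- read_expression_tsv(f)
  expect_equal(nrow(e), 2)
  expect_equal(e$expr_common[e$variant_id == "rs1"], 10)
  expect_equal(e$expr_alt[e$variant_id == "rs1"], 12)  # het by default
  hom <- read_expression_tsv(f, alt_genotype = "hom")
  expect_equal(hom$expr_alt[hom$variant_id == "rs1"], 14)
  blood <- read_expression_tsv(f, tissue_policy = "blood")
  expect_equal(blood$expr_common[blood$variant_id == "rs2"], 5)
})
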