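test_that("compositions count and normalize per sample", {
  preds <- tibble::tibble(sample_id = "s1", label = rep("Cyanophyta", 50))
  comp <- summarize_composition(preds)
  expect_equal(comp$proportion[comp$category == "Cyanophyta"], 1)

  preds2 <- tibble::tibble(
    sample_id = "s1",
    label = rep(c("a", "b", "c", "d"), times = c(33, 6, 9, 52)))
  comp2 <- summarize_composition(preds2)
  expect_equal(comp2$proportion, c(33, 6, 9, 52) / 100)
  expect_equal(sum(comp2$proportion), 1, tolerance = 1e-9)
  expect_equal(comp2$n, c(33L, 6L, 9L, 52L))

  # absent categories appear with zero counts
  comp3 <- summarize_composition(preds, categories = c("Cyanophyta", "x"))
  expect_equal(comp3$proportion[comp3$category == "x"], 0)
  expect_error(summarize_composition(preds[0, ]), "empty")
})

test_that("known mixtures are recovered within multinomial sampling error", {
  # a single draw lands outside the 2-SD band for one of 4 categories in
  # ~18 % of seeds, so the concentration claim is checked as coverage
  # across replicates: ~95 % of per-category errors must sit within 2 SD
  mixture <- c(a = 0.3, b = 0.1, c = 0.1, d = 0.5)
  n <- 5000
  sd_cat <- sqrt(mixture * (1 - mixture) / n)
  within <- vapply(1:20, function(r) {
    labels <- withr::with_seed(r, sample(names(mixture), n, TRUE, mixture))
    comp <- summarize_composition(tibble::tibble(sample_id = "s",
                                                 label = labels))
    err <- abs(comp$proportion - mixture[comp$category])
    mean(err <= 2 * sd_cat[comp$category])
  }, 0)
  expect_gte(mean(within), 0.85)
})

test_that("composition error shrinks with sample size", {
  mixture <- c(a = 0.3, b = 0.1, c = 0.1, d = 0.5)
  mean_err <- function(n) {
    errs <- vapply(1:5, function(r) {
      lab <- withr::with_seed(100 + r + n,
                              sample(names(mixture), n, TRUE, mixture))
      comp <- summarize_composition(tibble::tibble(sample_id = "s",
                                                   label = lab))
      max(abs(comp$proportion - mixture[comp$category]))
    }, 0)
    mean(errs)
  }
  errs <- c(mean_err(500), mean_err(5000), mean_err(50000))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[2], errs[1] * 1.5)
})

test_that("phylum renormalization reproduces the printed-table arithmetic", {
  comp <- tibble::tibble(
    sample_id = c(rep("CF-1", 4), rep("CF-4", 4)),
    category = rep(c("Cyanophyta", "Bacillariophyta", "Chlorophyta",
                     "other_SPM"), 2),
    proportion = c(0.3348, 0.0608, 0.0898, 0.5146,
                   0.0465, 0.0669, 0.3418, 0.5448))
  phyla <- renormalize_phyla(comp, drop = "other_SPM")
  cf1 <- phyla[phyla$sample_id == "CF-1", ]
  expect_equal(round(cf1$proportion, 4), c(0.6897, 0.1253, 0.1850))
  cf4 <- phyla[phyla$sample_id == "CF-4", ]
  expect_equal(round(cf4$proportion, 4), c(0.1022, 0.1470, 0.7509))
  # ratios among retained categories preserved
  expect_equal(cf1$proportion[1] / cf1$proportion[2], 0.3348 / 0.0608,
               tolerance = 1e-9)
  expect_equal(sum(cf1$proportion), 1, tolerance = 1e-9)
})

test_that("renormalization is idempotent and guards degenerate input", {
  comp <- summarize_composition(
    tibble::tibble(sample_id = "s",
                   label = rep(c("a", "b", "spm"), c(30, 20, 50))))
  r1 <- renormalize_phyla(comp, drop = "spm")
  r2 <- renormalize_phyla(r1, drop = "spm")
  expect_equal(r1$proportion, r2$proportion, tolerance = 1e-12)
  r0 <- renormalize_phyla(comp, drop = character(0))
  expect_equal(r0$proportion, comp$proportion, tolerance = 1e-12)
  zero <- tibble::tibble(sample_id = "s", category = c("a", "spm"),
                         proportion = c(0, 1))
  expect_error(renormalize_phyla(zero, drop = "spm"), "zero")
  expect_error(renormalize_phyla(comp, drop = c("a", "b", "spm")),
               "no retained")
})

test_that("dominance thresholds follow the field convention exactly", {
  out <- label_dominance(c(A = 0.12, B = 0.05, C = 0.005))
  expect_equal(out$status, c("dominant", "common", "neither"))
  expect_equal(label_dominance(c(A = 0.10))$status, "common")  # boundary
  expect_equal(label_dominance(c(A = 0.01))$status, "common")  # boundary
  expect_equal(label_dominance(c(A = 0.100001))$status, "dominant")
  expect_equal(nrow(label_dominance(numeric(0))), 0)
  expect_error(label_dominance(c(A = -0.1)), "negative")
  expect_error(label_dominance(c(A = 0.9, B = 0.2)), "sum")
})

test_that("dominance grids render the +++ / ++ marks", {
  labels <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 2),
    species = rep(c("N8", "N20"), 2),
    status = c("dominant", "common", "neither", "dominant"))
  grid <- dominance_grid(labels)
  expect_equal(grid$s1[grid$species == "N8"], "+++")
  expect_equal(grid$s2[grid$species == "N8"], "")
  expect_equal(grid$s2[grid$species == "N20"], "+++")
})

test_that("the correlation statistic matches its closed form and stats::cor", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8,
               tolerance = 1e-12)
  withr::local_seed(23)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15) + 0.5 * x
    expect_equal(pearson_r(x, y)$r, stats::cor(x, y), tolerance = 1e-12)
    expect_equal(pearson_r(x, y)$r, oracle_pearson(x, y), tolerance = 1e-12)
    # invariance under positive affine maps; sign flip under negation
    expect_equal(pearson_r(2 * x + 5, y)$r, pearson_r(x, y)$r,
                 tolerance = 1e-12)
    expect_equal(pearson_r(-x, y)$r, -pearson_r(x, y)$r, tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:3, 1:4), "mismatch")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})
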