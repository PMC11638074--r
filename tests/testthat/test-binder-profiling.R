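# Binder profiling: filtering, normalization, imputation, ANOVA + BH,
# Z scores, clustering.

make_im <- function(values, peptides = NULL, groups = NULL, log2 = TRUE) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  }
  if (is.null(peptides)) {
    peptides <- setNames(rep(5L, nrow(values)), rownames(values))
  }
  if (is.null(groups)) {
    groups <- rep(c("A", "B", "C"), length.out = ncol(values))
  }
  structure(list(values = values, unique_peptides = peptides,
                 groups = groups,
                 replicate = as.integer(ave(seq_along(groups), groups,
                                            FUN = seq_along)),
                 log2 = log2, truth = NULL),
            class = "intensity_matrix")
}

test_that("preprocessing filters, transforms and median-centers", {
  set.seed(1)
  v <- matrix(2^rnorm(60, 20, 2), 5, 12)
  rownames(v) <- paste0("P", 1:5)
  pep <- setNames(c(1L, 2L, 5L, 1L, 3L), rownames(v))
  m <- make_im(v, pep, log2 = FALSE)
  pre <- preprocess_intensity(m)
  expect_setequal(rownames(pre$values), c("P2", "P3", "P5"))
  meds <- apply(pre$values, 2, median, na.rm = TRUE)
  expect_true(all(abs(meds) < 1e-12))
  # centering equals the hand-computed shift
  expect_equal(pre$values[1, 1],
               log2(v["P2", 1]) - median(log2(v[c(2, 3, 5), 1])),
               tolerance = 1e-12)
  # all-missing sample rejected
  v2 <- v; v2[c(2, 3, 5), 1] <- NA
  expect_error(preprocess_intensity(make_im(v2, pep, log2 = FALSE)),
               "no observed")
})

test_that("imputation draws from the downshifted Gaussian, observed fixed", {
  set.seed(2)
  v <- matrix(rnorm(3000, 0, 1), 300, 10)
  v[sample(length(v), 900)] <- NA
  m <- make_im(v)
  imp <- impute_missing(m, seed = 10)
  mask <- is.na(v)
  expect_identical(imp$values[!mask], v[!mask])
  expect_false(anyNA(imp$values))
  # same seed, same completion; no seed side effects on observed
  imp2 <- impute_missing(m, seed = 10)
  expect_identical(imp$values, imp2$values)
  # no missing values: unchanged
  full <- make_im(matrix(rnorm(40), 4, 10))
  expect_identical(impute_missing(full, seed = 1)$values, full$values)
  # distribution check: per-sample imputed mean near median - 1.8 sd
  j <- 1
  obs <- v[!mask[, j], j]
  mu <- median(obs) - 1.8 * sd(obs)
  expect_lt(abs(mean(imp$values[mask[, j], j]) - mu),
            4 * 0.3 * sd(obs) / sqrt(sum(mask[, j])) + 0.05)
  # too few observed values: error
  tiny <- make_im(matrix(c(1, NA, NA, NA, NA, NA, 1, 2, 3, 4), 5, 2))
  expect_error(impute_missing(tiny, seed = 1), "fewer than 3")
})

test_that("per-protein ANOVA agrees with stats::aov and the t-test", {
  set.seed(3)
  v <- matrix(rnorm(10 * 9, 0, 1), 10, 9)
  g <- rep(c("A", "B", "C"), each = 3)
  m <- make_im(v, groups = g)
  res <- test_differential(m)
  for (i in c(1, 4, 7)) {
    fit <- summary(aov(v[i, ] ~ factor(g)))[[1]]
    expect_equal(res$F[i], fit$`F value`[1], tolerance = 1e-9)
    expect_equal(res$p[i], fit$`Pr(>F)`[1], tolerance = 1e-9)
  }
  # two equal-sized groups: F equals the square of the pooled t statistic
  g2 <- rep(c("A", "B"), each = 4)
  v2 <- matrix(rnorm(5 * 8), 5, 8)
  res2 <- test_differential(make_im(v2, groups = g2))
  for (i in 1:5) {
    tt <- t.test(v2[i, g2 == "A"], v2[i, g2 == "B"], var.equal = TRUE)
    expect_equal(res2$F[i], unname(tt$statistic)^2, tolerance = 1e-9)
  }
  # identical values in all samples: F = 0, not significant
  v3 <- rbind(rep(1, 9), v[1:2, ])
  res3 <- test_differential(make_im(v3, groups = g))
  expect_identical(res3$F[1], 0)
  expect_false(res3$significant[1])
  # BH monotonicity and p_adj >= p
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_error(test_differential(make_im(matrix(NA_real_, 2, 9),
                                         groups = g)),
               "missing")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(6)
  for (rep_ in 1:5) {
    p <- runif(sample(3:20, 1))^2
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # and the package path uses exactly that adjustment
  v <- matrix(rnorm(20 * 9), 20, 9)
  res <- test_differential(make_im(v))
  expect_equal(res$p_adj, bh_oracle(res$p), tolerance = 1e-12)
})

test_that("Z-scoring standardizes rows and rejects constant rows", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE)
  rownames(v) <- c("a", "b")
  z <- zscore_profiles(make_im(v))
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  # hand-computed 3-sample row
  expect_equal(unname(z[1, ]), (c(1, 2, 3) - 2) / 1, tolerance = 1e-12)
  vc <- rbind(v, cc = c(7, 7, 7))
  expect_error(zscore_profiles(make_im(vc)), "constant")
  # subsetting keeps only requested proteins
  z2 <- zscore_profiles(make_im(v), subset = "a")
  expect_identical(rownames(z2), "a")
})

test_that("hierarchical clustering is deterministic with sane edge cases", {
  set.seed(7)
  z <- matrix(rnorm(60), 10, 6)
  rownames(z) <- paste0("p", 1:10)
  colnames(z) <- paste0("s", 1:6)
  a <- cluster_profiles(z, k = 3)
  b <- cluster_profiles(z, k = 3)
  expect_identical(a$clusters, b$clusters)
  expect_identical(sort(unique(a$clusters)), 1:3)
  expect_setequal(a$protein_order, rownames(z))
  expect_setequal(a$sample_order, colnames(z))
  # k = 1: everything together
  expect_true(all(cluster_profiles(z, k = 1)$clusters == 1L))
  # duplicated rows sit in the same cluster (distance 0)
  zz <- rbind(z, p11 = z[1, ])
  cl <- cluster_profiles(zz, k = 5)
  expect_identical(unname(cl$clusters["p1"]), unname(cl$clusters["p11"]))
  expect_error(cluster_profiles(z, k = 11), "exceeds")
})

test_that("intensity matrix TSV round trip preserves data and metadata", {
  m <- simulate_dia_matrix(dia_design(n_proteins = 30L), seed = 4)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_intensity_matrix(m, tmp)
  r <- read_intensity_matrix(tmp)
  expect_equal(r$values, m$values, tolerance = 1e-6)
  expect_identical(r$groups, m$groups)
  expect_identical(unname(r$unique_peptides), unname(m$unique_peptides))
})
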