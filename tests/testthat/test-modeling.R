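noiseless_table <- function(seed = 2) {
  simulate_descriptor_table(noise_sigma = 0, seed = seed)
}

test_that("a noiseless linear response is recovered exactly", {
  tab <- noiseless_table()
  truth <- attr(tab, "planted")
  m <- fit_mlr(tab, truth$true_features)
  expect_equal(unname(m$coefficients_raw),
               unname(truth$true_coefficients), tolerance = 1e-10)
  ev <- evaluate_model(m, tab)
  expect_equal(ev$r2_train, 1, tolerance = 1e-12)
  expect_lt(ev$mae_train, 1e-10)
})

test_that("a constant response gives zero coefficients and mean intercept", {
  tab <- noiseless_table()
  tab$co2a <- 3.7
  m <- fit_mlr(tab, c("x1", "x2", "x3"))
  expect_equal(unname(m$coefficients), rep(0, 3), tolerance = 1e-12)
  expect_equal(m$intercept, 3.7)
})

test_that("degenerate feature sets raise collinearity errors naming features", {
  tab <- noiseless_table()
  tab$dup <- tab$x1
  err <- tryCatch(fit_mlr(tab, c("x1", "dup", "x2")), error = function(e) e)
  expect_s3_class(err, "co2screen_collinearity_error")
  tab$const <- 1
  expect_error(fit_mlr(tab, c("x1", "const")),
               class = "co2screen_collinearity_error")
  expect_error(fit_mlr(tab[1:3, ], c("x1", "x2", "x3")),
               class = "co2screen_input_error")
})

test_that("prediction at the training means returns the response mean", {
  tab <- simulate_descriptor_table(seed = 4)
  m <- fit_mlr(tab, c("x1", "x2", "x3"))
  center <- as.data.frame(as.list(colMeans(tab[, c("x1", "x2", "x3")])))
  expect_equal(predict(m, center), mean(tab$co2a), tolerance = 1e-10)
  # linearity: moving one feature moves the prediction by its raw slope
  shifted <- center; shifted$x1 <- shifted$x1 + 1
  expect_equal(predict(m, shifted) - predict(m, center),
               unname(m$coefficients_raw["x1"]), tolerance = 1e-10)
})

test_that("training R2 is invariant to affine rescaling of a feature", {
  tab <- simulate_descriptor_table(seed = 6)
  r2a <- evaluate_model(fit_mlr(tab, c("x1", "x2", "x3")), tab)$r2_train
  tab$x1 <- 100 * tab$x1 - 7
  r2b <- evaluate_model(fit_mlr(tab, c("x1", "x2", "x3")), tab)$r2_train
  expect_equal(r2a, r2b, tolerance = 1e-12)
})

test_that("coefficient estimates stay within 3 SEs of truth across seeds", {
  hits <- 0L; total <- 0L
  for (sd in 1:100) {
    tab <- simulate_descriptor_table(n_decoys = 0, seed = sd)
    truth <- attr(tab, "planted")$true_coefficients
    fit <- stats::lm(co2a ~ x1 + x2 + x3, data = tab)
    se <- summary(fit)$coefficients[-1, "Std. Error"]
    est <- stats::coef(fit)[-1]
    hits <- hits + sum(abs(est - truth) <= 3 * se)
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.99)
})

test_that("LOO predictions equal the hat-matrix closed form", {
  tab <- simulate_descriptor_table(n_samples = 12, seed = 8)
  feats <- c("x1", "x2", "x3")
  cv <- loo_cv(tab, feats)
  X <- cbind(1, as.matrix(tab[, feats]))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  resid <- tab$co2a - X %*% solve(crossprod(X), crossprod(X, tab$co2a))
  loo_oracle <- tab$co2a - resid / (1 - diag(H))
  expect_equal(cv$predictions, drop(loo_oracle), tolerance = 1e-9)
})

test_that("LOO separates signal from noise", {
  clean <- noiseless_table()
  expect_equal(loo_cv(clean, c("x1", "x2", "x3"))$q2_loo, 1,
               tolerance = 1e-10)
  q2s <- vapply(1:30, function(sd) {
    tab <- simulate_descriptor_table(n_samples = 20, seed = sd)
    tab$co2a <- with_seed_shuffle(tab$co2a, sd)  # break the relation
    loo_cv(tab, c("x1", "x2", "x3"))$q2_loo
  }, numeric(1))
  expect_lt(mean(q2s), 0)  # pure noise: Q2 non-positive in expectation
})

test_that("k-fold partitions are balanced, disjoint and seed-stable", {
  tab <- simulate_descriptor_table(seed = 10)  # n = 31
  a <- kfold_cv(tab, c("x1", "x2", "x3"), k = 5, seed = 3)
  expect_identical(sort(a$folds$n, decreasing = TRUE), c(7L, 6L, 6L, 6L, 6L))
  expect_identical(sort(unique(a$assignment)), 1:5)
  b <- kfold_cv(tab, c("x1", "x2", "x3"), k = 5, seed = 3)
  expect_identical(a$assignment, b$assignment)
  expect_equal(a$r2_pooled, b$r2_pooled)
  expect_error(kfold_cv(tab[1:4, ], c("x1", "x2", "x3"), k = 5),
               class = "co2screen_split_error")
})

test_that("subset search enumerates C(n,k) candidates and skips collinear ones", {
  tab <- noiseless_table()
  pool <- c("x1", "x2", "x3", "d1", "d2", "d3")
  res <- best_subset_search(tab, pool, subset_size = 3)
  expect_identical(nrow(res$leaderboard), 20L)  # C(6,3)
  expect_setequal(res$best_features, c("x1", "x2", "x3"))
  tab$dupx1 <- tab$x1
  res2 <- best_subset_search(tab, c(pool, "dupx1"), subset_size = 3)
  skipped <- res2$leaderboard[!is.na(res2$leaderboard$skipped), ]
  expect_identical(nrow(skipped), 5L)  # every subset pairing x1 with dupx1
  expect_true(all(grepl("dupx1", skipped$features) &
                  grepl("x1\\+", skipped$features)))
  expect_error(best_subset_search(tab, pool, 3, cap = 5),
               class = "co2screen_cap_exceeded")
})

test_that("the HOMO filter is inclusive at the threshold", {
  expect_true(homo_filter(-0.129))    # proceeds to round 2
  expect_false(homo_filter(-0.153))   # screened out
  expect_true(homo_filter(-0.140))    # boundary passes
  expect_identical(homo_filter(c(-0.1, -0.2)), c(TRUE, FALSE))
  expect_error(homo_filter(NaN), class = "co2screen_input_error")
})

test_that("adding a pure-noise feature never lowers training R2", {
  worse <- 0L
  for (sd in 1:50) {
    tab <- simulate_descriptor_table(n_samples = 25, seed = sd)
    set.seed(sd + 5000)
    tab$noise <- rnorm(nrow(tab))
    r2_base <- evaluate_model(fit_mlr(tab, c("x1", "x2", "x3")), tab)$r2_train
    r2_plus <- evaluate_model(fit_mlr(tab, c("x1", "x2", "x3", "noise")),
                              tab)$r2_train
    if (r2_plus < r2_base - 1e-12) worse <- worse + 1L
  }
  expect_identical(worse, 0L)
})

test_that("nucleophilicity correlation handles exact, degenerate and unpaired input", {
  aff <- data.frame(id = letters[1:5], co2a = c(1, 3, 5, 7, 9))
  nv <- data.frame(id = letters[1:5], N = c(10, 11, 12, 13, 14))
  res <- nucleophilicity_correlation(aff, nv)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  expect_equal(res$slope, 2)
  nv$N <- 5
  expect_error(nucleophilicity_correlation(aff, nv),
               class = "co2screen_degenerate_input")
  expect_error(nucleophilicity_correlation(aff, data.frame(id = letters[2:6],
                                                           N = 1:5)),
               class = "co2screen_join_error")
})

test_that("models round-trip through their text serialization", {
  tab <- simulate_descriptor_table(seed = 12)
  m <- fit_mlr(tab, c("x1", "x2", "x3"))
  f <- tempfile(fileext = ".json")
  write_mlr_model(m, f)
  back <- read_mlr_model(f)
  expect_equal(predict(back, tab), predict(m, tab), tolerance = 1e-12)
  expect_identical(back$feature_names, m$feature_names)
})
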