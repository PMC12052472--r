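test_that("shapiro_wilk wraps the test and rejects bad input", {
  sw <- shapiro_wilk(1:50)
  expect_lt(sw$statistic, 1)
  expect_true(sw$p_value >= 0 && sw$p_value <= 1)
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  # right-skewed sample flagged as non-normal (the screening the pipeline
  # relies on before reaching for non-parametric tests)
  set.seed(7)
  x <- exp(rnorm(100))
  expect_lt(shapiro_wilk(x)$p_value, 0.05)
})

test_that("iqr_filter removes the planted upper outlier, keeps order", {
  r <- iqr_filter(c(1:10, 1000))
  expect_equal(r$retained, 1:10)
  expect_equal(r$removed, 1000)
  # all-equal sample: bounds collapse to the value, nothing removed
  r <- iqr_filter(rep(4, 6))
  expect_equal(r$retained, rep(4, 6))
  expect_length(r$removed, 0)
  # in-bounds sample is untouched, in input order
  x <- c(3, 1, 2, 5, 4)
  expect_equal(iqr_filter(x)$retained, x)
  expect_error(iqr_filter(1:3), "at least 4")
  expect_error(outlier_policy(lower_multiplier = 3, upper_multiplier = 1.5))
})

test_that("iqr_filter asymmetry tolerates the right tail more", {
  # Q1 = 6, Q3 = 16, IQR = 10: 40 exceeds Q3 + 1.5 IQR = 31 but not
  # Q3 + 3 IQR = 46, so only the symmetric policy removes it
  x <- c(1:20, 40)
  pol <- outlier_policy(1.5, 3)
  expect_true(40 %in% iqr_filter(x, pol)$retained)
  sym <- outlier_policy(1.5, 1.5)
  expect_false(40 %in% iqr_filter(x, sym)$retained)
  # refiltering a stable sample changes nothing (single-pass contract)
  ret <- iqr_filter(c(1:10, 1000))$retained
  expect_equal(iqr_filter(ret)$retained, ret)
})

test_that("bootstrap_mean_diff: degenerate, power and determinism", {
  b0 <- bootstrap_mean_diff(rep(5, 10), rep(5, 12), 1000, seed = 1)
  expect_equal(b0$estimate, 0)
  expect_equal(c(b0$lower, b0$upper), c(0, 0))

  set.seed(3)
  a <- rnorm(200, 10); b <- rnorm(200, 7)
  r1 <- bootstrap_mean_diff(a, b, 1000, seed = 2)
  expect_true(r1$lower <= r1$estimate && r1$estimate <= r1$upper)
  expect_true(r1$lower > 0)            # excludes zero at this effect size
  expect_true(r1$lower < 3 && r1$upper > 3)
  r2 <- bootstrap_mean_diff(a, b, 1000, seed = 2)
  expect_identical(r1, r2)
  expect_error(bootstrap_mean_diff(numeric(0), 1:3, 1000, seed = 1),
               "non-empty")
  expect_error(bootstrap_mean_diff(1:3, 1:3, 50, seed = 1), "at least 100")
})

test_that("bootstrap resampling leaves the caller's RNG state alone", {
  set.seed(123)
  before <- .Random.seed
  invisible(bootstrap_mean_diff(rnorm(10), rnorm(10), 1000, seed = 9))
  set.seed(123)
  expect_identical(before, .Random.seed)
})

test_that("ks_exact: printed toy case and degenerate identity", {
  r <- ks_exact(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$statistic, 1)
  expect_identical(r$p_value, 0.1)      # 2 of the C(6,3)=20 arrangements
  expect_true(r$exact)
  r <- ks_exact(c(1, 2, 2, 5), c(5, 2, 1, 2))
  expect_identical(r$statistic, 0)
  expect_identical(r$p_value, 1)
})

test_that("ks_exact equals brute-force enumeration, with and without ties", {
  set.seed(14)
  for (i in 1:5) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    a <- rnorm(n); b <- rnorm(m, 0.6)             # continuous
    expect_equal(ks_exact(a, b)$p_value, ks_brute(a, b)$p_value,
                 tolerance = 1e-12)
    a <- sample(1:4, n, TRUE); b <- sample(2:5, m, TRUE)  # heavy ties
    expect_equal(ks_exact(a, b)$p_value, ks_brute(a, b)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("ks_exact agrees with stats::psmirnov across sizes", {
  set.seed(25)
  for (i in 1:8) {
    n <- sample(4:40, 1); m <- sample(4:40, 1)
    a <- rnorm(n); b <- rnorm(m, 0.4)
    r <- ks_exact(a, b)
    # psmirnov gives P(D < q) exactly on the lattice, so the observed
    # tail P(D >= d_obs) is its complement
    expect_equal(r$p_value,
                 1 - psmirnov(r$statistic, c(n, m), two.sided = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("ks_exact falls back to the asymptotic tail above the guard", {
  set.seed(31)
  a <- rnorm(150); b <- rnorm(150, 0.3)
  r <- ks_exact(a, b)                   # n*m = 22500 > 10000
  expect_false(r$exact)
  ref <- suppressWarnings(ks.test(a, b, exact = FALSE)$p.value)
  expect_equal(r$p_value, ref, tolerance = 1e-6)
})

test_that("spearman_rho matches a mid-rank oracle on ties", {
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  expect_equal(spearman_rho(1:5, c(2, 4, 8, 16, 32)), 1)
  set.seed(6)
  x <- sample(1:5, 30, TRUE); y <- sample(1:5, 30, TRUE)
  midrank <- function(v) rank(v, ties.method = "average")
  oracle <- cor(midrank(x), midrank(y))
  expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("harmonic_mean_p: closed forms, bounds, permutation invariance", {
  expect_equal(harmonic_mean_p(c(0.05, 0.05, 0.05)), 0.05)
  expect_equal(harmonic_mean_p(c(0.01, 0.1, 1)), 3 / 111)
  expect_equal(harmonic_mean_p(0.37), 0.37)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    h <- harmonic_mean_p(p)
    expect_gte(h, min(p))
    expect_lte(h, max(p))
    expect_equal(harmonic_mean_p(sample(p)), h, tolerance = 1e-15)
  }
  expect_error(harmonic_mean_p(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(harmonic_mean_p(numeric(0)), "at least one")
})

test_that("calibrated HMP tracks the simulated null of k uniform p-values", {
  set.seed(10)
  raw <- replicate(4000, harmonic_mean_p(runif(3)))
  for (x in c(0.05, 0.2)) {
    expect_equal(eggscore:::.hmp_null_tail(x, 3), mean(raw <= x),
                 tolerance = 0.15)
  }
  # calibration de-biases the anti-conservative raw mean at small values
  expect_gt(harmonic_mean_p(c(0.01, 0.02, 0.03), calibrated = TRUE),
            harmonic_mean_p(c(0.01, 0.02, 0.03)))
})

test_that("pairwise_compare builds symmetric matrices and combined p", {
  set.seed(12)
  recs <- data.frame(
    egg_id = rep(c("e1", "e2", "e3"), each = 8),
    complexity = c(rnorm(8, 10), rnorm(8, 10), rnorm(8, 20)),
    relief = c(rnorm(8, 5), rnorm(8, 5), rnorm(8, 9)),
    orientation = rnorm(24, 30, 5))
  pm <- pairwise_compare(recs)
  expect_setequal(names(pm$matrices),
                  c("complexity", "relief", "orientation", "combined"))
  for (m in pm$matrices) {
    expect_identical(m, t(m))
    expect_equal(diag(m), c(e1 = 1, e2 = 1, e3 = 1))
    expect_true(all(m > 0 & m <= 1))
  }
  # combined value equals the harmonic mean of the per-metric entries
  mets <- c("complexity", "relief", "orientation")
  h <- harmonic_mean_p(vapply(mets, function(k) pm$matrices[[k]]["e1", "e3"], 0))
  expect_equal(pm$matrices$combined["e1", "e3"], h)
  # e3 is well separated from e1 and e2 on two of three metrics
  expect_lt(pm$matrices$combined["e1", "e3"], 0.05)
  expect_gt(pm$matrices$combined["e1", "e2"], 0.05)

  # an egg with one section is excluded with a warning
  recs1 <- rbind(recs, data.frame(egg_id = "e4", complexity = 1, relief = 1,
                                  orientation = 1))
  expect_warning(pm2 <- pairwise_compare(recs1), "e4")
  expect_setequal(pm2$labels, c("e1", "e2", "e3"))
})

test_that("pairwise CSV export writes long and matrix forms", {
  set.seed(13)
  recs <- data.frame(egg_id = rep(c("a", "b"), each = 5),
                     complexity = rnorm(10), relief = rnorm(10),
                     orientation = rnorm(10))
  pm <- pairwise_compare(recs)
  d <- withr::local_tempdir()
  paths <- write_pairwise_csv(pm, d)
  expect_true(all(file.exists(paths)))
  long <- read.csv(file.path(d, "pairwise_long.csv"))
  expect_named(long, c("egg_a", "egg_b", "metric", "p_value"))
  expect_equal(nrow(long), 4)  # one pair x (3 metrics + combined)
})
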