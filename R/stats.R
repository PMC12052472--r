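#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] used to screen each egg's
#' metric distributions before the non-parametric comparisons.  The
#' result is reported, never used to switch methods silently.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("Shapiro-Wilk undefined for a constant sample", call. = FALSE)
  ht <- shapiro.test(x)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Asymmetric IQR outlier policy
#'
#' Metric distributions on ornamented surfaces are right-skewed, so the
#' screen uses a larger multiplier on the upper bound than on the lower:
#' values below `Q1 - lower_multiplier * IQR` or above
#' `Q3 + upper_multiplier * IQR` are removed.  Quartiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7);
#' the convention matters because it changes which points are outliers.
#'
#' @param lower_multiplier IQR multiple below Q1 (default 1.5).
#' @param upper_multiplier IQR multiple above Q3 (default 3; the larger
#'   upper multiplier tolerates the right tail).
#' @param quantile_type quartile convention, passed to
#'   [stats::quantile()].
#' @return an object of class `outlier_policy`.
#' @export
outlier_policy <- function(lower_multiplier = 1.5, upper_multiplier = 3,
                           quantile_type = 7) {
  if (!(upper_multiplier >= lower_multiplier && lower_multiplier > 0))
    stop("need upper_multiplier >= lower_multiplier > 0", call. = FALSE)
  structure(list(lower_multiplier = lower_multiplier,
                 upper_multiplier = upper_multiplier,
                 quantile_type = quantile_type),
            class = "outlier_policy")
}

#' Remove IQR outliers from a sample
#'
#' Single-pass filter under an [outlier_policy()]; the order of retained
#' values is preserved.
#'
#' @param x numeric sample, n >= 4.
#' @param policy an [outlier_policy()].
#' @return list with `retained`, `removed`, and the `bounds` used.
#' @export
iqr_filter <- function(x, policy = outlier_policy()) {
  x <- as.numeric(x)
  if (length(x) < 4L)
    stop("IQR filtering needs at least 4 values (got ", length(x), ")",
         call. = FALSE)
  q <- quantile(x, c(0.25, 0.75), names = FALSE,
                type = policy$quantile_type, na.rm = TRUE)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - policy$lower_multiplier * iqr
  hi <- q[2L] + policy$upper_multiplier * iqr
  keep <- !is.na(x) & x >= lo & x <= hi
  list(retained = x[keep], removed = x[!keep & !is.na(x)],
       bounds = c(lower = lo, upper = hi))
}

#' Bootstrap percentile CI for a difference in means
#'
#' Resamples each group with replacement `iterations` times and returns
#' the percentile 95% confidence interval of `mean(a) - mean(b)`.
#' Reproducible for a given `seed`; the RNG state of the caller is left
#' untouched.
#'
#' @param a,b numeric samples (non-empty).
#' @param iterations bootstrap replicates, >= 100 (default 1000).
#' @param seed integer seed (required for reproducibility).
#' @return an object of class `bootstrap_result`: list with `estimate`,
#'   `lower`, `upper`, `iterations`, `seed`.
#' @export
bootstrap_mean_diff <- function(a, b, iterations = 1000, seed) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (iterations < 100L)
    stop("`iterations` must be at least 100", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  diffs <- .with_seed(seed, {
    ma <- colMeans(matrix(sample(a, length(a) * iterations, replace = TRUE),
                          nrow = length(a)))
    mb <- colMeans(matrix(sample(b, length(b) * iterations, replace = TRUE),
                          nrow = length(b)))
    ma - mb
  })
  ci <- quantile(diffs, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(estimate = mean(a) - mean(b),
                 lower = ci[1L], upper = ci[2L],
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("mean difference %.4f, 95%% CI [%.4f, %.4f] (%d iterations)\n",
              x$estimate, x$lower, x$upper, x$iterations))
  invisible(x)
}

# evaluate expr under a temporary RNG seed, restoring caller state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Exact two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs.  The
#' p-value is computed exactly by counting, over all
#' `choose(n + m, n)` equally likely assignments of the pooled values to
#' the two groups, the fraction whose D statistic reaches the observed
#' one.  The count runs over a dynamic program on the lattice of partial
#' group sizes; ties in the pooled sample are handled by conditioning on
#' the observed multiset (the ECDF distance is only evaluated where the
#' pooled value changes).  All lattice comparisons are integer, so the
#' test is immune to floating-point ties.  Above the feasibility guard
#' `n * m > exact_limit` the asymptotic Kolmogorov distribution is used
#' and flagged in the result.
#'
#' @param a,b numeric samples (unequal lengths allowed).
#' @param exact_limit largest `n * m` for which the exact enumeration is
#'   attempted (default 10000).
#' @return an object of class `ks_exact_result`: list with `statistic`
#'   (D), `p_value`, `exact` (logical), `n`, `m`.
#' @export
ks_exact <- function(a, b, exact_limit = 10000) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("samples must not contain NA", call. = FALSE)

  vals <- sort(unique(c(a, b)))
  ca <- tabulate(match(a, vals), nbins = length(vals))
  cb <- tabulate(match(b, vals), nbins = length(vals))
  cum_a <- cumsum(ca); cum_b <- cumsum(cb)
  # integer numerator of |F_a - F_b| on the common denominator n*m
  dnum <- max(abs(cum_a * m - cum_b * n))
  D <- dnum / (n * m)

  if (dnum == 0L) {
    return(structure(list(statistic = 0, p_value = 1, exact = TRUE,
                          n = n, m = m), class = "ks_exact_result"))
  }
  if (as.double(n) * m <= exact_limit) {
    p <- .ks_exact_p(ca + cb, n, m, dnum)
    exact <- TRUE
  } else {
    t <- sqrt(n * m / (n + m)) * D
    k <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
    exact <- FALSE
  }
  structure(list(statistic = D, p_value = p, exact = exact, n = n, m = m),
            class = "ks_exact_result")
}

#' @export
print.ks_exact_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.6g, p = %.6g (%s; n = %d, m = %d)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "asymptotic", x$n, x$m))
  invisible(x)
}

# P(D >= dnum/(n*m)) by counting lattice paths through the tie blocks.
# blocks: pooled multiplicity of each distinct value. State i = values
# assigned to sample a so far; a path is excluded once |i*m - j*n| >= dnum
# at a block boundary.  Counts stay exact in doubles up to ~1e15 paths per
# cell and C(200,100) ~ 9e58 fits double range.
.ks_exact_p <- function(blocks, n, m, dnum) {
  g <- c(1, numeric(n))      # g[i+1] = #valid paths with i values in a
  tot <- 0L
  for (ct in blocks) {
    new <- numeric(n + 1L)
    for (k in 0:min(ct, n)) {
      w <- choose(ct, k)
      if (k == 0) {
        new <- new + g * w
      } else {
        src <- seq_len(n + 1L - k)
        new[src + k] <- new[src + k] + g[src] * w
      }
    }
    tot <- tot + ct
    i <- 0:n
    j <- tot - i
    bad <- j < 0L | j > m | abs(i * m - j * n) >= dnum
    new[bad] <- 0
    g <- new
  }
  total <- choose(n + m, n)
  (total - g[n + 1L]) / total
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties); used to
#' assess the inter-relationship of the three metrics.
#'
#' @param x,y numeric samples of equal length, n >= 3.
#' @return the correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("Spearman correlation needs n >= 3", call. = FALSE)
  cor(x, y, method = "spearman")
}

#' Harmonic-mean p-value
#'
#' Combines the p-values of the three (non-independent) metric tests
#' into one summary value, the unweighted harmonic mean
#' `k / sum(1 / p_i)`.  The harmonic mean always lies between the
#' smallest and largest input and weights small p-values heavily without
#' assuming independence.  The raw harmonic mean is mildly
#' anti-conservative as a test statistic; `calibrated = TRUE` instead
#' returns `P(HMP_k <= observed)` under the null of k independent
#' uniform p-values, computed by exact quadrature of the k-fold
#' convolution for k <= 5 and by a large fixed-seed Monte Carlo sample
#' for larger k.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param calibrated return the calibrated null tail probability instead
#'   of the raw harmonic mean.  Default `FALSE` (the raw mean is what is
#'   compared against the significance threshold).
#' @return a single combined p-value.
#' @export
harmonic_mean_p <- function(p, calibrated = FALSE) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("need at least one p-value", call. = FALSE)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  hmp <- if (length(p) == 1L) p else length(p) / sum(1 / p)
  if (!calibrated) return(hmp)
  .hmp_null_tail(hmp, length(p))
}

# P(harmonic mean of k iid U(0,1) p-values <= x)
# = P(sum of k iid Pareto(1) variables >= k / x)
.hmp_null_tail <- function(x, k) {
  if (k == 1L) return(x)
  t <- k / x
  if (k <= 5L) .pareto_sum_tail(k, t)
  else {
    draws <- .with_seed(20260920L, matrix(1 / runif(k * 200000L), nrow = k))
    mean(colSums(draws) >= t)
  }
}

# P(X1 + ... + Xk >= t) for iid Pareto(1) (density 1/x^2 on [1, Inf)),
# by recursive adaptive quadrature; exact small-k null of the HMP.
.pareto_sum_tail <- function(k, t) {
  if (k == 1L) return(if (t <= 1) 1 else 1 / t)
  if (t <= k) return(1)
  upper <- t - (k - 1)   # beyond this, X1 alone pushes the sum over t
  tail_rest <- function(s) vapply(s, function(si) .pareto_sum_tail(k - 1L, si),
                                  0)
  int <- stats::integrate(function(x) tail_rest(t - x) / x^2,
                          lower = 1, upper = upper,
                          rel.tol = 1e-9, subdivisions = 400L)$value
  1 / upper + int
}

#' Pairwise per-egg comparison matrices
#'
#' For every unordered pair of eggs, runs [ks_exact()] on each metric's
#' per-section values and combines the per-metric p-values with
#' [harmonic_mean_p()].  Returns symmetric p-value matrices per metric
#' plus the combined matrix, and the fraction of pairs whose combined
#' p-value falls below `alpha`.
#'
#' @param records data frame of score records (as from [score_batch()]),
#'   with an egg identifier column and one column per metric.
#' @param alpha significance threshold (default 0.05).
#' @param metrics metric columns to compare.
#' @param group_col column identifying the egg (default `"egg_id"`).
#' @param calibrated passed to [harmonic_mean_p()].
#' @return an object of class `pairwise_matrix`: list with `labels`,
#'   `matrices` (named list of symmetric p-value matrices, including
#'   `"combined"`; diagonal 1), `pairs` (long-format data frame
#'   `egg_a, egg_b, metric, p_value`), `alpha` and
#'   `significant_fraction`.  Eggs with fewer than 2 sections are
#'   excluded with a warning.
#' @export
pairwise_compare <- function(records, alpha = 0.05,
                             metrics = c("complexity", "relief", "orientation"),
                             group_col = "egg_id", calibrated = FALSE) {
  stopifnot(is.data.frame(records), group_col %in% names(records),
            all(metrics %in% names(records)))
  by_egg <- split(records, records[[group_col]])
  sizes <- vapply(by_egg, nrow, 0L)
  if (any(sizes < 2L)) {
    warning("excluding egg(s) with fewer than 2 sections: ",
            paste(names(by_egg)[sizes < 2L], collapse = ", "))
    by_egg <- by_egg[sizes >= 2L]
  }
  eggs <- names(by_egg)
  k <- length(eggs)
  if (k < 2L) stop("need at least 2 eggs with >= 2 sections", call. = FALSE)

  mats <- lapply(c(metrics, "combined"), function(i) {
    m <- matrix(NA_real_, k, k, dimnames = list(eggs, eggs))
    diag(m) <- 1
    m
  })
  names(mats) <- c(metrics, "combined")
  long <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      pvs <- vapply(metrics, function(met) {
        va <- by_egg[[i]][[met]]; vb <- by_egg[[j]][[met]]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (length(va) < 2L || length(vb) < 2L) return(NA_real_)
        ks_exact(va, vb)$p_value
      }, 0)
      comb <- if (anyNA(pvs)) NA_real_ else harmonic_mean_p(pvs, calibrated)
      for (met in metrics) {
        mats[[met]][i, j] <- mats[[met]][j, i] <- pvs[[met]]
      }
      mats[["combined"]][i, j] <- mats[["combined"]][j, i] <- comb
      long[[length(long) + 1L]] <-
        data.frame(egg_a = eggs[i], egg_b = eggs[j],
                   metric = c(metrics, "combined"),
                   p_value = c(unname(pvs), comb),
                   stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, long)
  comb_p <- pairs$p_value[pairs$metric == "combined"]
  structure(list(labels = eggs, matrices = mats, pairs = pairs,
                 alpha = alpha,
                 significant_fraction = mean(comb_p < alpha, na.rm = TRUE)),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  np <- length(x$labels) * (length(x$labels) - 1) / 2
  cat(sprintf(
    "<pairwise_matrix> %d eggs, %d pairs; %.0f%% significant at alpha = %g\n",
    length(x$labels), np, 100 * x$significant_fraction, x$alpha))
  invisible(x)
}

#' Export pairwise matrices as CSV
#'
#' Writes the long-format table (`egg_a, egg_b, metric, p_value`) and one
#' square-matrix CSV per metric (for heatmap rendering).
#'
#' @param pm a [pairwise_compare()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_pairwise_csv <- function(pm, dir, prefix = "pairwise") {
  stopifnot(inherits(pm, "pairwise_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_long.csv"))
  .write_csv_bytes(pm$pairs, paths)
  for (met in names(pm$matrices)) {
    p <- file.path(dir, paste0(prefix, "_matrix_", met, ".csv"))
    m <- pm$matrices[[met]]
    df <- data.frame(egg = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .write_csv_bytes(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# deterministic CSV writer (binary connection, fixed number formatting)
.write_csv_bytes <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  fmt_col <- function(col) {
    if (is.numeric(col) && !is.integer(col)) .num_str(col) else as.character(col)
  }
  cells <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(cells, 1L, paste, collapse = ","), con)
  invisible(path)
}
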