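# Delaporte model estimation and the moderated Fisher's exact test.
#
# Observed promoter count X = S + B: S ~ NB(r, p) is the methylation signal,
# B ~ Poisson(lambda) the non-specific background measured in the promoter's
# background windows. X is then Delaporte(alpha = r, beta = (1 - p)/p, lambda).

#' Estimate the Poisson background rate per promoter
#'
#' `lambda_i = mean_j b_ij`: the arithmetic mean of the (normalized)
#' background counts across the replicates of one condition.
#'
#' @param b Background counts: matrix or data frame (promoters x replicates),
#'   or a count table with an id column.
#' @return Named numeric vector of per-promoter `lambda` estimates.
#' @export
estimate_lambda <- function(b) {
  m <- background_matrix(b)
  rowMeans(m)
}

background_matrix <- function(b) {
  if (is.data.frame(b) && !is.numeric(b[[1L]])) return(as_count_matrix(b))
  as.matrix(b)
}

#' Moment estimates of the methylation signal
#'
#' For each promoter, from observed counts `x` and background counts `b`
#' across the replicates of one condition:
#' `mu_S = max(mean(x) - mean(b), 0)` and
#' `var_S = var(x) + var(b) - 2 rho sd(x) sd(b)`, with `rho` the replicate-
#' level Pearson correlation of x and b clamped to `[0, 1]` (0 when fewer
#' than 3 replicates or when either variance vanishes). `var_S` is floored at
#' a small positive `eps`.
#'
#' @param x,b Promoter-by-replicate matrices of observed and background
#'   counts (same shape; normalized counts are fine).
#' @param eps Floor for the signal variance.
#' @return A tibble with columns `mu_s`, `var_x`, `var_b`, `rho`, `var_s`,
#'   `mean_x`, `mean_b`, `clamped` (TRUE where the raw `mu_S` was negative).
#' @export
signal_moments <- function(x, b, eps = 1e-8) {
  x <- background_matrix(x); b <- background_matrix(b)
  if (!all(dim(x) == dim(b))) abort("`x` and `b` must have the same replicate structure")
  m <- ncol(x)
  mean_x <- rowMeans(x); mean_b <- rowMeans(b)
  if (m < 2L) {
    var_x <- var_b <- rep(NA_real_, nrow(x))
  } else {
    var_x <- rowSums((x - mean_x)^2) / (m - 1)
    var_b <- rowSums((b - mean_b)^2) / (m - 1)
  }
  if (m >= 3L) {
    cov_xb <- rowSums((x - mean_x) * (b - mean_b)) / (m - 1)
    denom <- sqrt(var_x * var_b)
    rho <- ifelse(is.finite(denom) & denom > 0, cov_xb / denom, 0)
    rho <- clamp(rho, 0, 1)
  } else {
    rho <- rep(0, nrow(x))
  }
  raw_mu <- mean_x - mean_b
  var_s <- pmax(var_x + var_b - 2 * rho * sqrt(var_x * var_b), eps)
  tibble::tibble(
    mu_s = pmax(raw_mu, 0), var_x = var_x, var_b = var_b, rho = rho,
    var_s = var_s, mean_x = mean_x, mean_b = mean_b, clamped = raw_mu < 0
  )
}

#' Moderated (trend-adjusted) signal variance
#'
#' With few replicates the per-promoter variance is unstable, so a smooth
#' mean-variance trend `v(mu)` is fitted across promoters by local regression
#' and each promoter's variance is shrunk upward to it:
#' `var_S_adj = max(var_S, v(mu_S))`, then clamped above `mu_S + eps` so the
#' negative-binomial moment equations stay defined.
#'
#' The trend is fitted on the log scale (per-promoter sample variances are
#' heavy-tailed chi-square quantities, which would dominate a raw-scale fit);
#' when the replicate count `m` is supplied, the chi-square log bias
#' `digamma((m-1)/2) - log((m-1)/2)` is removed so the trend targets the
#' underlying variance rather than its geometric mean.
#'
#' @param mu_s,var_s Per-promoter signal means and variances (one condition).
#' @param min_trend Minimum number of promoters with `mu_s > 0` needed to fit
#'   the trend; below it (or on trend failure) a 75th-percentile
#'   variance-to-mean scaling is used with a warning.
#' @param eps Clamp margin.
#' @param m Replicate count behind the `var_s` estimates (optional, enables
#'   the log-scale bias correction).
#' @return Numeric vector `var_s_adj`, with the fitted trend attached as
#'   attribute `trend` (a function of `mu`).
#' @export
adjusted_variance <- function(mu_s, var_s, min_trend = 50L, eps = 1e-8,
                              m = NULL) {
  stopifnot(length(mu_s) == length(var_s))
  idx <- which(mu_s > 0 & is.finite(var_s) & var_s > 0)
  bias <- if (!is.null(m) && m >= 2) {
    df <- m - 1
    digamma(df / 2) - log(df / 2)
  } else 0
  trend_fun <- NULL
  if (length(idx) >= min_trend) {
    lmu <- log1p(mu_s[idx])
    lv <- log(var_s[idx])
    fit <- tryCatch(
      loess(lv ~ lmu, span = 0.6, degree = 2, family = "gaussian"),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rng <- range(lmu)
      trend_fun <- function(mu) {
        z <- clamp(log1p(mu), rng[1], rng[2])
        exp(predict(fit, newdata = data.frame(lmu = z)) - bias)
      }
    }
  }
  if (is.null(trend_fun)) {
    warn("variance trend unavailable; using 75th-percentile variance/mean scaling")
    ratio <- if (length(idx) > 0) {
      quantile(var_s[idx] / mu_s[idx], 0.75, names = FALSE)
    } else 1
    trend_fun <- function(mu) ratio * mu
  }
  v <- trend_fun(mu_s)
  v[!is.finite(v)] <- 0
  adj <- pmax(var_s, v, na.rm = TRUE)
  adj <- pmax(adj, mu_s + eps, mu_s * (1 + 1e-8))
  attr(adj, "trend") <- trend_fun
  adj
}

#' Non-parametric (moment) Delaporte parameter estimates
#'
#' `r = mu^2 / (var' - mu)` and `p = mu / var'` from the adjusted signal
#' moments, with `alpha = r` and `beta = (1 - p)/p = 1/p - 1`. Promoters with
#' `mu_s = 0` get a degenerate signal (point mass at zero, flagged); as
#' `var' -> mu` the NB approaches its Poisson limit and `r` is capped at 1e8
#' with a flag.
#'
#' @param mu_s,var_s_adj,lambda Vectors of signal means, adjusted variances
#'   and background rates per promoter.
#' @return A tibble with columns `r`, `p`, `alpha`, `beta`, `lambda`,
#'   `regime` (`"nonparametric"`), `degenerate`, `poisson_cap`.
#' @export
np_estimate <- function(mu_s, var_s_adj, lambda) {
  n <- length(mu_s)
  stopifnot(length(var_s_adj) == n, length(lambda) == n)
  degenerate <- !(mu_s > 0)
  beta <- ifelse(degenerate, 0, var_s_adj / pmax(mu_s, 1e-300) - 1)
  beta <- pmax(beta, 0)
  r <- ifelse(degenerate, 1e-8, ifelse(beta > 0, mu_s / beta, Inf))
  poisson_cap <- is.finite(r) & r > 1e8 | is.infinite(r)
  r <- pmin(r, 1e8)
  beta <- ifelse(poisson_cap & !degenerate, mu_s / r, beta)
  p <- 1 / (1 + beta)
  tibble::tibble(
    r = r, p = p, alpha = r, beta = beta, lambda = lambda,
    regime = "nonparametric", degenerate = degenerate,
    poisson_cap = poisson_cap & !degenerate
  )
}

#' Joint Delaporte maximum-likelihood estimation
#'
#' Maximizes the joint likelihood of the observed counts (Delaporte) and the
#' background counts (Poisson, shared `lambda`) over `(alpha, beta, lambda)`
#' with BFGS on log-parameters, initialized from the moment estimates. Used
#' when the replicate number exceeds the regime threshold (more than 5 by
#' default in [run_dm()]).
#'
#' @param x Observed counts for one promoter across replicates (rounded to
#'   integers internally).
#' @param b Matching background counts (may be non-integer after
#'   normalization; a continuous Poisson log-likelihood is used).
#' @param init Optional named list `alpha`, `beta`, `lambda` of starting
#'   values.
#' @return A one-row tibble like [np_estimate()]'s, with `regime = "mle"`,
#'   plus `loglik` and `converged`. Falls back to the moment estimates with a
#'   warning if the optimizer fails.
#' @export
mle_estimate <- function(x, b, init = NULL) {
  x <- round(x)
  lam0 <- mean(b)
  if (all(x == 0)) {
    out <- np_estimate(0, 1e-8, lam0)
    out$regime <- "mle"
    out$loglik <- NA_real_
    out$converged <- FALSE
    return(out)
  }
  if (is.null(init)) {
    mu0 <- max(mean(x) - lam0, 0.5)
    v0 <- max(var(x), mu0 * 1.2)
    beta0 <- max(v0 / mu0 - 1, 0.05)
    init <- list(alpha = mu0 / beta0, beta = beta0, lambda = max(lam0, 1e-3))
  }
  par0 <- log(c(init$alpha, init$beta, init$lambda))
  bad_par <- function(a, be, la) {
    !all(is.finite(c(a, be, la))) || a > 1e9 || be > 1e9 || la > 1e9 ||
      a < 1e-9 || be < 1e-12 || la < 1e-12
  }
  nll <- function(par) {
    a <- exp(par[1]); be <- exp(par[2]); la <- exp(par[3])
    if (bad_par(a, be, la)) return(1e10)
    lx <- sum(vapply(x, function(k) delap_inner(k, a, be, la)$lp, numeric(1)))
    lb <- sum(b * log(la) - la - lgamma(b + 1))
    v <- -(lx + lb)
    if (!is.finite(v)) 1e10 else v
  }
  ngr <- function(par) {
    a <- exp(par[1]); be <- exp(par[2]); la <- exp(par[3])
    if (bad_par(a, be, la)) return(c(0, 0, 0))
    parts <- lapply(x, delap_inner, alpha = a, beta = be, lambda = la,
                    grad = TRUE)
    da <- sum(vapply(parts, `[[`, numeric(1), "da"))
    db <- sum(vapply(parts, `[[`, numeric(1), "db"))
    dl <- sum(vapply(parts, `[[`, numeric(1), "dl")) + sum(b / la - 1)
    g <- -c(da * a, db * be, dl * la)   # chain rule to log-parameters
    if (!all(is.finite(g))) c(0, 0, 0) else g
  }
  opt <- tryCatch(
    optim(par0, nll, gr = ngr, method = "BFGS",
          control = list(maxit = 200, reltol = 1e-7)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    warn("Delaporte MLE failed; falling back to the non-parametric estimates")
    mu0 <- max(mean(x) - lam0, 0)
    out <- np_estimate(mu0, max(var(x), mu0 + 1e-8), lam0)
    out$loglik <- NA_real_
    out$converged <- FALSE
    return(out)
  }
  a <- exp(opt$par[1]); be <- exp(opt$par[2]); la <- exp(opt$par[3])
  tibble::tibble(
    r = a, p = 1 / (1 + be), alpha = a, beta = be, lambda = la,
    regime = "mle", degenerate = FALSE, poisson_cap = FALSE,
    loglik = -opt$value, converged = opt$convergence == 0
  )
}

#' Moderated Fisher's exact test for two Delaporte models
#'
#' Conditions on the pooled total `n = x + y` and enumerates all splits
#' `a + b = n`, scoring each by `p(a, b) = P_A(a) P_B(b)` under the two
#' fitted Delaporte models. The p-value is the total probability of splits no
#' more probable than the observed one:
#' `p = sum_{p(a,b) <= p(x,y)} p(a,b) / sum_all p(a,b)`.
#'
#' @param x,y Pooled (normalized, rounded) counts for the two conditions.
#' @param fit_a,fit_b Delaporte parameters for the pooled conditions: lists or
#'   one-row data frames with `alpha`, `beta`, `lambda` (replicate pooling
#'   multiplies `alpha` and `lambda` by the replicate count).
#' @return The p-value, in `(0, 1]`; `x + y = 0` gives 1.
#' @export
moderated_fisher_test <- function(x, y, fit_a, fit_b) {
  if (x < 0 || y < 0) abort("counts must be non-negative")
  n <- as.integer(x + y)
  if (n == 0L) return(1)
  if (n > 1e6) abort("x + y exceeds the enumeration cap of 1e6")
  fa <- as.list(fit_a)[c("alpha", "beta", "lambda")]
  fb <- as.list(fit_b)[c("alpha", "beta", "lambda")]
  band <- fisher_band(fa, fb, n, x, tail = 1e-16)
  if (is.null(band)) band <- fisher_band(fa, fb, n, x, tail = 1e-120)
  if (is.null(band)) return(1e-300)
  den <- sum(band$paxy)
  mx <- max(band$paxy)
  if (!(den > 0)) return(1e-300)
  reliable <- if (band$exact) band$pobs > 0 else band$pobs >= mx * 1e-9
  if (reliable) {
    return(min(1, sum(band$paxy[band$paxy <= band$pobs]) / den))
  }
  # Observation deeper than the band resolves (the actual data can be far
  # more dispersed than the fitted model): score it with the exact log pmf
  # and bound the numerator by its two-tail leading term. Only the ranking
  # of such extreme promoters matters, and it is preserved.
  lpobs <- ddelap_log_one(x, fa$alpha, fa$beta, fa$lambda) +
    ddelap_log_one(y, fb$alpha, fb$beta, fb$lambda)
  p <- 2 * exp(lpobs) / den
  clamp(p, 1e-300, 1)
}

# The conditional slice p(a, n - a) over the region where both factors carry
# mass. Narrow component bands take the exact convolution route; wide bands
# are sampled on a stride-G lattice anchored at the observed count via the
# characteristic-function transform (the strided sums approximate the full
# enumeration sums with relative error O((G/sigma)^2)).
fisher_band <- function(fa, fb, n, x, tail) {
  # supports stay untruncated: the transform period must cover the whole
  # distribution or the beyond-n tail aliases into the window
  sA <- delap_support(fa$alpha, fa$beta, fa$lambda, tail = tail)
  sB <- delap_support(fb$alpha, fb$beta, fb$lambda, tail = tail)
  a_lo <- max(sA$lo, n - sB$hi, 0L)
  a_hi <- min(sA$hi, n - sB$lo, n)
  if (a_lo > a_hi) return(NULL)
  exact_ok <- min(sA$w_nb, sA$w_po) <= 256L && min(sB$w_nb, sB$w_po) <= 256L
  if (exact_ok) {
    A <- delap_pmf_band(fa$alpha, fa$beta, fa$lambda, kmax = n, tail = tail)
    B <- delap_pmf_band(fb$alpha, fb$beta, fb$lambda, kmax = n, tail = tail)
    avec <- a_lo:a_hi
    paxy <- A$pmf[avec - A$offset + 1L] * B$pmf[(n - avec) - B$offset + 1L]
    pobs <- if (x >= a_lo && x <= a_hi) paxy[x - a_lo + 1L] else 0
    return(list(paxy = paxy, pobs = pobs,
                exact = isTRUE(attr(A$pmf, "exact")) &&
                  isTRUE(attr(B$pmf, "exact"))))
  }
  width <- a_hi - a_lo + 1L
  G <- bitwShiftL(1L, max(0L, ceiling(log2(width / 2048))))
  n_bins <- (a_hi - a_lo) %/% G + 1L
  mA <- delap_bin_masses(fa$alpha, fa$beta, fa$lambda, a_lo, G, n_bins, sA)
  # B's bins pair exactly with A's: bin j of A covers a in
  # [a_lo + G j, a_lo + G j + G - 1], so its partner covers n - a
  mB <- rev(delap_bin_masses(fb$alpha, fb$beta, fb$lambda,
                             n - a_lo - G * n_bins + 1L, G, n_bins, sB))
  paxy <- mA * mB
  x_in <- x >= a_lo && x <= a_hi
  pobs <- if (x_in) paxy[(x - a_lo) %/% G + 1L] else 0
  list(paxy = paxy, pobs = pobs, exact = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (a thin wrapper over [stats::p.adjust()]).
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise no smaller than `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential methylation testing between two conditions
#'
#' The full testing pipeline: median-of-ratios normalization (shared between
#' promoter and background tables), per-condition background rates (Poisson
#' mean of the background counts), signal moment estimation with the
#' trend-adjusted variance, Delaporte parameters per promoter and condition
#' (moment estimates, or joint MLE when the replicate number exceeds
#' `mle_threshold`), the moderated Fisher's exact test on pooled normalized
#' counts, a log2 fold change of background-subtracted means, and BH
#' adjustment.
#'
#' @param promoter_counts Count table (`promoter_id` + sample columns) of
#'   reads in TSS +/- 2 kb windows.
#' @param background_counts Count table of per-promoter background sums
#'   ([background_counts_per_promoter()]). Promoters absent here (no
#'   background windows) are excluded from testing and reported in the
#'   `excluded` attribute.
#' @param conditions Two-column data frame (`sample`, `condition`) or named
#'   vector; exactly two conditions, each with at least 2 replicates.
#' @param mle_threshold Replicate count above which the MLE regime is used
#'   (default 5).
#' @param pseudocount Pseudocount for the log2 fold change (default 1).
#' @param min_trend Passed to [adjusted_variance()].
#' @param sf Optional precomputed size factors (named as the samples).
#' @return A tibble of class `mbd_dm_result` with one row per tested
#'   promoter: `promoter_id`, `mean_a`, `mean_b` (background-subtracted
#'   normalized signal means), `x`, `y` (pooled normalized counts),
#'   `log2_fc`, `p_value`, `p_adj`, `lambda_a`, `lambda_b`, `regime`.
#'   Attributes: `conditions` (the two labels, in order a/b), `excluded`
#'   (promoter ids without background).
#' @examples
#' sim <- simulate_mbd_dataset(n_promoters = 100, m_per_group = 3, seed = 1)
#' res <- run_dm(sim$promoter_counts, sim$background_counts, sim$conditions)
#' head(res[order(res$p_value), ])
#' @export
run_dm <- function(promoter_counts, background_counts, conditions,
                   mle_threshold = 5L, pseudocount = 1, min_trend = 50L,
                   sf = NULL) {
  X <- as_count_matrix(promoter_counts, "promoter counts")
  B <- as_count_matrix(background_counts, "background counts")
  samples <- colnames(X)
  if (!setequal(colnames(B), samples)) {
    abort("promoter and background tables must share the same samples")
  }
  B <- B[, samples, drop = FALSE]
  cond <- condition_vector(conditions, samples)
  lv <- unique(cond)
  if (length(lv) != 2L) abort("exactly two conditions are required")
  m_by <- table(factor(cond, levels = lv))
  if (any(m_by < 2L)) abort("each condition needs at least 2 replicates")

  common <- intersect(rownames(X), rownames(B))
  excluded <- setdiff(rownames(X), common)
  X <- X[common, , drop = FALSE]
  B <- B[common, , drop = FALSE]

  if (is.null(sf)) sf <- size_factors(promoter_counts)
  sf <- sf[samples]
  xn <- sweep(X, 2L, sf, "/")
  bn <- sweep(B, 2L, sf, "/")

  fits <- lapply(lv, function(g) {
    fit_condition(xn[, cond == g, drop = FALSE],
                  bn[, cond == g, drop = FALSE],
                  mle_threshold = mle_threshold, min_trend = min_trend)
  })
  m_a <- as.integer(m_by[[1L]]); m_b <- as.integer(m_by[[2L]])
  x_pool <- round(rowSums(xn[, cond == lv[1L], drop = FALSE]))
  y_pool <- round(rowSums(xn[, cond == lv[2L], drop = FALSE]))

  # Null hypothesis of the exact test: both conditions share a common signal
  # mean (the across-all-samples background-subtracted mean), while each
  # condition keeps its own dispersion (beta) and background rate (lambda).
  mu_0 <- pmax(rowMeans(xn) - rowMeans(bn), 0)
  # The NB dispersion phi (var = mu + phi mu^2) is scale-free, so it can be
  # shared between the two conditions (halving the sampling noise of the
  # noisiest estimate at small m) without letting a true fold change inflate
  # the null variance; the shared value is evaluated at the common null mean.
  phi_a <- null_phi(fits[[1L]])
  phi_b <- null_phi(fits[[2L]])
  phi_0 <- dplyr::coalesce((phi_a + phi_b) / 2, phi_a, phi_b, 0)
  beta_0 <- ifelse(mu_0 > 0, pmax(phi_0 * mu_0, 1e-8), 0)
  alpha_a0 <- alpha_b0 <- ifelse(mu_0 > 0, pmin(mu_0 / beta_0, 1e8), 1e-8)
  beta_a0 <- beta_b0 <- beta_0

  p_value <- vapply(seq_along(common), function(i) {
    fa <- list(alpha = alpha_a0[i] * m_a, beta = beta_a0[i],
               lambda = fits[[1L]]$lambda[i] * m_a)
    fb <- list(alpha = alpha_b0[i] * m_b, beta = beta_b0[i],
               lambda = fits[[2L]]$lambda[i] * m_b)
    moderated_fisher_test(x_pool[i], y_pool[i], fa, fb)
  }, numeric(1))

  out <- tibble::tibble(
    promoter_id = common,
    mean_a = fits[[1L]]$mu_s, mean_b = fits[[2L]]$mu_s,
    x = x_pool, y = y_pool,
    log2_fc = log2((fits[[2L]]$mu_s + pseudocount) /
                     (fits[[1L]]$mu_s + pseudocount)),
    p_value = p_value,
    p_adj = bh_adjust(p_value),
    lambda_a = fits[[1L]]$lambda, lambda_b = fits[[2L]]$lambda,
    regime = fits[[1L]]$regime
  )
  class(out) <- c("mbd_dm_result", class(out))
  attr(out, "conditions") <- lv
  attr(out, "excluded") <- excluded
  if (length(excluded) > 0L) {
    inform(sprintf("%d promoter(s) without background windows excluded from testing",
                   length(excluded)))
  }
  out
}

# Scale-free NB dispersion phi = (var - mu)/mu^2 of one condition's fit
# (1/alpha under the MLE regime, since var = mu(1 + beta) and mu = alpha
# beta); NA where the condition carries no usable signal estimate.
null_phi <- function(est) {
  phi <- ifelse(est$regime == "mle", 1 / est$alpha,
                (est$var_s_adj - est$mu_s) / est$mu_s^2)
  ifelse(!est$degenerate & est$mu_s > 0, pmax(phi, 1e-12), NA_real_)
}

# Per-condition model fit on normalized matrices.
fit_condition <- function(x, b, mle_threshold = 5L, min_trend = 50L) {
  m <- ncol(x)
  lambda <- rowMeans(b)
  mom <- signal_moments(x, b)
  var_adj <- adjusted_variance(mom$mu_s, mom$var_s, min_trend = min_trend, m = m)
  est <- np_estimate(mom$mu_s, as.numeric(var_adj), lambda)
  est$mu_s <- mom$mu_s
  est$var_s <- mom$var_s
  est$var_s_adj <- as.numeric(var_adj)
  attr(est, "trend") <- attr(var_adj, "trend")
  if (m > mle_threshold) {
    for (i in seq_len(nrow(est))) {
      if (est$degenerate[i]) next
      fit <- mle_estimate(x[i, ], b[i, ],
                          init = list(alpha = est$alpha[i],
                                      beta = max(est$beta[i], 1e-3),
                                      lambda = max(est$lambda[i], 1e-3)))
      if (isTRUE(fit$converged)) {
        est$alpha[i] <- fit$alpha; est$beta[i] <- fit$beta
        est$r[i] <- fit$r; est$p[i] <- fit$p
        est$lambda[i] <- fit$lambda
        est$regime[i] <- "mle"
      }
    }
  }
  est
}

#' @export
autoplot.mbd_dm_result <- function(object, alpha = 0.05, ...) {
  df <- object
  df$significant <- df$p_adj < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "log2 fold change (background-subtracted)",
                  y = "-log10 p-value",
                  colour = sprintf("adj. p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}
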