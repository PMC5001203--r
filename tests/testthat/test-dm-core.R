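test_that("estimate_lambda is the replicate mean", {
  expect_equal(unname(estimate_lambda(matrix(c(2, 4, 6), nrow = 1))), 4)
  expect_equal(unname(estimate_lambda(matrix(0, 1, 3))), 0)
  withr::with_seed(31, {
    b <- matrix(rpois(50 * 4, 7), 50, 4)
  })
  expect_equal(unname(estimate_lambda(b)), rowMeans(b))
})

test_that("signal moments handle constant inputs, clamping and rho = 0", {
  m <- signal_moments(matrix(10, 1, 3), matrix(2, 1, 3))
  expect_equal(m$mu_s, 8)
  expect_equal(m$var_x, 0)
  expect_equal(m$var_b, 0)
  expect_equal(m$var_s, 1e-8)
  expect_false(m$clamped)

  # background above observation clamps to zero with a flag
  m2 <- signal_moments(matrix(c(1, 2, 3), 1, 3), matrix(c(9, 9, 9), 1, 3))
  expect_equal(m2$mu_s, 0)
  expect_true(m2$clamped)

  # independent x and b with rho forced 0: var_s = var_x + var_b
  withr::with_seed(32, {
    x <- matrix(rpois(200 * 2, 50), 200, 2)  # m = 2 < 3 -> rho = 0
    b <- matrix(rpois(200 * 2, 10), 200, 2)
  })
  m3 <- signal_moments(x, b)
  expect_equal(m3$rho, rep(0, 200))
  expect_equal(m3$var_s, pmax(m3$var_x + m3$var_b, 1e-8))
})

test_that("adjusted variance recovers a known quadratic mean-variance law", {
  withr::with_seed(33, {
    mu <- rlnorm(2000, log(300), 1)
    law <- mu + 0.4 * mu^2
    m_rep <- 6L
    var_obs <- law * rchisq(2000, df = m_rep - 1) / (m_rep - 1)
  })
  adj <- adjusted_variance(mu, var_obs, m = m_rep)
  trend <- attr(adj, "trend")
  central <- mu > quantile(mu, 0.05) & mu < quantile(mu, 0.95)
  rel <- abs(trend(mu[central]) - law[central]) / law[central]
  expect_lt(quantile(rel, 0.9), 0.10)
  # max rule
  expect_true(all(adj >= pmax(var_obs, 0), na.rm = TRUE))
  expect_true(all(adj > mu))
  hi <- var_obs > 2 * trend(mu)
  expect_equal(as.numeric(adj)[hi], var_obs[hi])
})

test_that("adjusted variance falls back gracefully with few promoters", {
  expect_warning(adj <- adjusted_variance(c(10, 20), c(30, 80)), "trend")
  expect_true(all(adj >= c(30, 80)))
})

test_that("np_estimate inverts the NB moment equations", {
  est <- np_estimate(10, 20, 5)
  expect_equal(est$r, 10)
  expect_equal(est$p, 0.5)
  expect_equal(est$alpha, est$r)
  expect_equal(est$p, 1 / (est$beta + 1), tolerance = 1e-9)

  # Poisson limit: var -> mu gives capped r
  est2 <- np_estimate(10, 10 + 1e-9, 5)
  expect_equal(est2$r, 1e8)
  expect_true(est2$poisson_cap)

  # degenerate signal
  est3 <- np_estimate(0, 1e-8, 2)
  expect_true(est3$degenerate)

  withr::with_seed(34, {
    mu <- runif(50, 5, 500)
    v <- mu * runif(50, 1.5, 30)
  })
  est4 <- np_estimate(mu, v, rep(1, 50))
  expect_equal(est4$alpha, est4$r)
  expect_lt(max(abs(est4$p - 1 / (est4$beta + 1))), 1e-9)
  # moment round-trip: alpha*beta = mu, alpha*beta*(1+beta) = v
  expect_equal(est4$alpha * est4$beta, mu, tolerance = 1e-9)
  expect_equal(est4$alpha * est4$beta * (1 + est4$beta), v, tolerance = 1e-6)
})

test_that("the joint MLE recovers Delaporte parameters at large m", {
  # A single m = 200 dataset leaves ~25% sampling error on the NB shape
  # parameters, so recovery is judged on the estimator's mean over
  # independent datasets (the full 20-dataset version runs with the
  # end-to-end checks); lambda is tight per dataset.
  fits <- lapply(1:6, function(s) {
    withr::with_seed(1000 + s, {
      m <- 200L
      x <- rnbinom(m, size = 2, prob = 1 / 2.5) + rpois(m, 3)
      b <- rpois(m, 3)
    })
    fit <- mle_estimate(x, b)
    expect_true(fit$converged)
    expect_lt(abs(fit$lambda - 3) / 3, 0.15)
    expect_gt(fit$alpha, 0.8); expect_lt(fit$alpha, 4)
    expect_gt(fit$beta, 0.6); expect_lt(fit$beta, 3.5)
    fit
  })

  # ascent: the optimum dominates the moment initializer
  withr::with_seed(1001, {
    x <- rnbinom(200, size = 2, prob = 1 / 2.5) + rpois(200, 3)
    b <- rpois(200, 3)
  })
  fit <- mle_estimate(x, b)
  loglik <- function(a, be, la) {
    sum(vapply(x, mbdcapdm:::ddelap_log_one, numeric(1),
               alpha = a, beta = be, lambda = la)) +
      sum(dpois(b, la, log = TRUE))
  }
  lam0 <- mean(b)
  mu0 <- max(mean(x) - lam0, 0.5)
  beta0 <- max(var(x) / mu0 - 1, 0.05)
  expect_gte(fit$loglik + 1e-6, loglik(mu0 / beta0, beta0, lam0))
})

test_that("with zero background the MLE approaches the pure NB fit", {
  skip_if_not_installed("MASS")
  withr::with_seed(43, {
    x <- rnbinom(300, size = 3, mu = 12)
  })
  fit <- mle_estimate(x, rep(0, 300))
  expect_lt(fit$lambda, 0.05)
  nb <- MASS::fitdistr(x, "negative binomial")
  size_hat <- unname(nb$estimate["size"])
  mu_hat <- unname(nb$estimate["mu"])
  expect_lt(abs(fit$alpha - size_hat) / size_hat, 0.05)
  expect_lt(abs(fit$alpha * fit$beta + fit$lambda - mu_hat) / mu_hat, 0.02)
})

test_that("lambda estimates are unbiased under a pure Poisson background", {
  withr::with_seed(44, {
    lam_true <- 6
    b <- matrix(rpois(3000 * 3, lam_true), 3000, 3)
  })
  lam_hat <- estimate_lambda(b)
  mc_se <- sd(lam_hat) / sqrt(length(lam_hat))
  expect_lt(abs(mean(lam_hat) - lam_true), 2 * mc_se)
})

test_that("moderated Fisher test agrees with brute-force enumeration", {
  expect_equal(moderated_fisher_test(0, 0, list(alpha = 1, beta = 1, lambda = 1),
                                     list(alpha = 1, beta = 1, lambda = 1)), 1)
  withr::with_seed(45, {
    for (i in 1:25) {
      fa <- list(alpha = runif(1, 0.5, 15), beta = runif(1, 0.05, 4),
                 lambda = runif(1, 0, 25))
      fb <- list(alpha = runif(1, 0.5, 15), beta = runif(1, 0.05, 4),
                 lambda = runif(1, 0, 25))
      x <- rdelap(1, fa$alpha, fa$beta, fa$lambda)
      y <- rdelap(1, fb$alpha, fb$beta, fb$lambda)
      if (x + y > 200) next
      expect_equal(moderated_fisher_test(x, y, fa, fb),
                   fisher_oracle(x, y, fa, fb), tolerance = 1e-12)
    }
  })
})

test_that("symmetric fits with equal counts sit at the conditional mode", {
  fit <- list(alpha = 6, beta = 2, lambda = 10)
  # verify (20, 20) is the modal split by enumeration, then p must be 1
  pa <- ddelap(0:40, fit$alpha, fit$beta, fit$lambda)
  pab <- pa * rev(pa)
  expect_equal(which.max(pab) - 1L, 20L)
  expect_equal(moderated_fisher_test(20, 20, fit, fit), 1)
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(46, p <- runif(100))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(-0.1, 0.5)), "0, 1")
})

test_that("run_dm returns near-1 p-values for identical conditions", {
  withr::with_seed(47, {
    base <- matrix(rnbinom(300 * 3, mu = 200, size = 5), 300, 3)
    bg <- matrix(rpois(300 * 3, 40), 300, 3)
  })
  X <- cbind(base, base)
  B <- cbind(bg, bg)
  colnames(X) <- colnames(B) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  rownames(X) <- rownames(B) <- sprintf("P%03d", 1:300)
  pc <- mbdcapdm:::matrix_to_tbl(X + B)
  bc <- mbdcapdm:::matrix_to_tbl(B)
  conds <- tibble::tibble(sample = colnames(X),
                          condition = rep(c("A", "B"), each = 3))
  res <- run_dm(pc, bc, conds)
  expect_true(all(res$p_value >= 0.99))
  expect_true(all(res$log2_fc == 0))
})

test_that("run_dm validates its design requirements", {
  pc <- tibble::tibble(promoter_id = c("P1", "P2"),
                       a1 = c(5, 6), b1 = c(7, 8))
  bc <- pc
  conds <- tibble::tibble(sample = c("a1", "b1"), condition = c("A", "B"))
  expect_error(run_dm(pc, bc, conds), "2 replicates")
})

test_that("promoters without background are excluded and reported", {
  withr::with_seed(48, {
    X <- matrix(rnbinom(100 * 4, mu = 300, size = 5), 100, 4)
    B <- matrix(rpois(100 * 4, 50), 100, 4)
  })
  colnames(X) <- colnames(B) <- c("a1", "a2", "b1", "b2")
  rownames(X) <- rownames(B) <- sprintf("P%03d", 1:100)
  pc <- mbdcapdm:::matrix_to_tbl(X)
  bc <- mbdcapdm:::matrix_to_tbl(B[-(1:5), ])  # P001-P005 have no background
  conds <- tibble::tibble(sample = colnames(X),
                          condition = c("A", "A", "B", "B"))
  res <- suppressMessages(run_dm(pc, bc, conds))
  expect_equal(nrow(res), 95L)
  expect_setequal(attr(res, "excluded"), sprintf("P%03d", 1:5))
})
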