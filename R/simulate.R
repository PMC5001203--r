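# Synthetic MBDCap-seq promoter/background count generation.
#
# Signal: per-promoter NB draws with (mean, dispersion) resampled from a
# parameter pool. Background: per-window hybrid noise, B_inc ~ M * Normal(mu,
# sigma) with mu ~ Poisson(lambda + NF), truncated at zero and rounded; a
# promoter's background is the sum over its windows. Observed count X = S + B.

#' Synthetic NB parameter table
#'
#' A deterministic stand-in for negative-binomial (mean, dispersion) estimates
#' from a real MBDCap-seq promoter count dataset, which are not publicly
#' available. Scales are chosen so that, under the standard hybrid noise model
#' (whose per-promoter background over 40 windows is several hundred reads at
#' the low-noise setting), the background distribution coincides with the
#' lower mode of the promoter count distribution, as observed in real
#' MBDCap-seq data: promoter means log-normal around 1200 reads (sdlog 1),
#' dispersions (`1/size`; variance `mu + phi mu^2`) log-normal around 0.3
#' (sdlog 0.6), typical of small-replicate capture experiments after trimming
#' the worst decile.
#'
#' @param n Number of rows (default 6000).
#' @param seed Seed for the deterministic table (fixed default so the shipped
#'   table is reproducible).
#' @return A tibble with columns `mean`, `dispersion`.
#' @export
synthetic_param_table <- function(n = 6000L, seed = 20160818L) {
  withr::with_seed(seed %% 2000000000L, {
    tibble::tibble(
      mean = rlnorm(n, meanlog = log(1200), sdlog = 1),
      dispersion = rlnorm(n, meanlog = log(0.3), sdlog = 0.6)
    )
  })
}

#' Build the simulation parameter pool
#'
#' Discards low-count promoters (`mean < min_mean`) and the top dispersion
#' decile, then samples `n` (mean, dispersion) pairs with replacement.
#'
#' @param params Parameter table with columns `mean`, `dispersion`
#'   (default: [synthetic_param_table()]).
#' @param n Pool size (default 5000).
#' @param seed Integer seed.
#' @param min_mean Low-count exclusion threshold (default 100 reads).
#' @param max_disp_quantile Dispersion exclusion quantile (default 0.9: the
#'   top 10% are dropped).
#' @return A tibble with `n` rows and columns `mean`, `dispersion`.
#' @export
build_param_pool <- function(params = synthetic_param_table(), n = 5000L,
                             seed = 1L, min_mean = 100,
                             max_disp_quantile = 0.9) {
  stopifnot(all(c("mean", "dispersion") %in% names(params)))
  if (nrow(params) < 100L) abort("parameter table needs at least 100 rows")
  cut <- quantile(params$dispersion, max_disp_quantile, names = FALSE)
  keep <- params[params$mean >= min_mean & params$dispersion <= cut, ]
  if (nrow(keep) == 0L) abort("exclusion rules removed every row")
  withr::with_seed(seed %% 2000000000L, {
    keep[sample.int(nrow(keep), n, replace = TRUE), ]
  })
}

#' Simulate the true methylation signal
#'
#' NB draws per promoter and replicate for two groups. A `dm_fraction` of
#' promoters is differentially methylated: their group-B mean is multiplied
#' or divided by `fold_change` (direction randomized per promoter). A fold
#' change of 1 yields no DM labels. `signal_dist = "normal"` instead draws
#' from a normal with the same mean and variance (truncated at 0, rounded),
#' for model-misspecification studies.
#'
#' @param pool Parameter pool from [build_param_pool()].
#' @param m_per_group Replicates per group.
#' @param dm_fraction Fraction of DM promoters.
#' @param fold_change Enrichment fold change for DM promoters.
#' @param seed Integer seed.
#' @param signal_dist `"nb"` (default) or `"normal"`.
#' @return A list with matrices `s_a`, `s_b` (promoters x replicates) and a
#'   tibble `truth` (`promoter_id`, `mean`, `dispersion`, `dm`, `fold`,
#'   `direction`).
#' @export
simulate_signal <- function(pool, m_per_group = 3L, dm_fraction = 0.1,
                            fold_change = 2, seed = 1L, signal_dist = "nb") {
  n <- nrow(pool)
  signal_dist <- match.arg(signal_dist, c("nb", "normal"))
  withr::with_seed(seed %% 2000000000L, {
    dm <- rep(FALSE, n)
    if (fold_change != 1 && dm_fraction > 0) {
      dm[sample.int(n, floor(dm_fraction * n))] <- TRUE
    }
    up <- runif(n) < 0.5
    fold_b <- ifelse(dm, ifelse(up, fold_change, 1 / fold_change), 1)
    mu_a <- pool$mean
    mu_b <- pool$mean * fold_b
    disp_rep <- rep(pool$dispersion, m_per_group)
    draw <- function(mu) {
      mu_rep <- rep(mu, m_per_group)
      if (signal_dist == "nb") {
        v <- rnbinom(n * m_per_group, mu = mu_rep, size = 1 / disp_rep)
      } else {
        sdv <- sqrt(mu_rep + disp_rep * mu_rep^2)
        v <- round(pmax(rnorm(n * m_per_group, mu_rep, sdv), 0))
      }
      matrix(v, nrow = n, ncol = m_per_group)
    }
    s_a <- draw(mu_a)
    s_b <- draw(mu_b)
    list(
      s_a = s_a, s_b = s_b,
      truth = tibble::tibble(
        promoter_id = sprintf("P%05d", seq_len(n)),
        mean = mu_a, dispersion = pool$dispersion,
        dm = dm, fold = fold_b,
        direction = ifelse(dm, ifelse(up, "up", "down"), "none")
      )
    )
  })
}

#' Simulate per-window background noise
#'
#' The hybrid model: per window and replicate, draw `mu ~ Poisson(lambda +
#' NF)` then `B_inc = M * Normal(mu, sigma)`, truncated at zero and rounded
#' to the nearest integer. `NF` inflates the Poisson rate (0 low, 7
#' intermediate, 20 high noise). `noise_model = "normal"` draws `mu` from a
#' normal with mean `lambda + NF` (sd `sqrt(lambda + NF)`), `"uniform"` from
#' `U(0, 2(lambda + NF))`, for misspecification studies.
#'
#' @param n_windows Number of windows.
#' @param m Number of replicates.
#' @param lambda Per-window Poisson base rate: scalar or length-`n_windows`
#'   vector.
#' @param nf Noise factor (0, 7 or 20 in the standard scenarios).
#' @param M Multiplier (default 10).
#' @param sigma Normal SD (default 3).
#' @param seed Integer seed.
#' @param noise_model `"poisson"` (default), `"normal"` or `"uniform"`.
#' @return Integer matrix (`n_windows` x `m`) of non-negative counts.
#' @export
simulate_window_noise <- function(n_windows, m, lambda = 0.5, nf = 0,
                                  M = 10, sigma = 3, seed = 1L,
                                  noise_model = "poisson") {
  noise_model <- match.arg(noise_model, c("poisson", "normal", "uniform"))
  stopifnot(M > 0, sigma >= 0, nf >= 0, all(lambda >= 0))
  withr::with_seed(seed %% 2000000000L, {
    total <- n_windows * m
    rate <- rep(lambda + nf, length.out = n_windows)
    rate_rep <- rep(rate, m)
    mu <- switch(noise_model,
      poisson = rpois(total, rate_rep),
      normal = pmax(rnorm(total, rate_rep, sqrt(pmax(rate_rep, 1e-8))), 0),
      uniform = runif(total, 0, 2 * rate_rep)
    )
    val <- M * rnorm(total, mu, sigma)
    matrix(as.integer(round(pmax(val, 0))), nrow = n_windows, ncol = m)
  })
}

#' Assemble a simulated dataset
#'
#' Sums each promoter's window noise into its background count `B`, sets the
#' observed count `X = S + B`, and exposes the same window draws as the
#' observable background (set `independent_observation = TRUE` to redraw the
#' observation independently for robustness studies).
#'
#' @param signal Output of [simulate_signal()].
#' @param noise_a,noise_b Window-noise matrices ([simulate_window_noise()])
#'   with `windows_per_promoter * n_promoters` rows.
#' @param windows_per_promoter Windows per promoter (default 40).
#' @param obs_noise_a,obs_noise_b Optional independent observation draws.
#' @return A list of count tables `promoter_counts`, `background_counts`,
#'   a `conditions` tibble, and the `truth` tibble.
#' @export
assemble_dataset <- function(signal, noise_a, noise_b,
                             windows_per_promoter = 40L,
                             obs_noise_a = NULL, obs_noise_b = NULL) {
  n <- nrow(signal$s_a)
  stopifnot(nrow(noise_a) == n * windows_per_promoter,
            nrow(noise_b) == n * windows_per_promoter)
  grp <- rep(seq_len(n), each = windows_per_promoter)
  b_a <- rowsum(noise_a, grp)
  b_b <- rowsum(noise_b, grp)
  x_a <- signal$s_a + b_a
  x_b <- signal$s_b + b_b
  ob_a <- if (is.null(obs_noise_a)) b_a else rowsum(obs_noise_a, grp)
  ob_b <- if (is.null(obs_noise_b)) b_b else rowsum(obs_noise_b, grp)
  ids <- signal$truth$promoter_id
  m_a <- ncol(x_a); m_b <- ncol(x_b)
  sam <- c(paste0("A", seq_len(m_a)), paste0("B", seq_len(m_b)))
  X <- cbind(x_a, x_b); colnames(X) <- sam; rownames(X) <- ids
  Bm <- cbind(ob_a, ob_b); colnames(Bm) <- sam; rownames(Bm) <- ids
  list(
    promoter_counts = matrix_to_tbl(X),
    background_counts = matrix_to_tbl(Bm),
    conditions = tibble::tibble(sample = sam,
                                condition = rep(c("A", "B"), c(m_a, m_b))),
    truth = signal$truth,
    signal = signal
  )
}

#' One-call simulated MBDCap-seq dataset
#'
#' Convenience wrapper chaining [build_param_pool()], [simulate_signal()],
#' [simulate_window_noise()] and [assemble_dataset()] under one seed. The
#' per-window base rates `lambda` are drawn once per dataset from an
#' exponential law with mean `window_lambda_mean`.
#'
#' @inheritParams simulate_signal
#' @inheritParams simulate_window_noise
#' @param n_promoters Number of promoters (default 5000).
#' @param pool Optional pre-built parameter pool (rows are recycled to
#'   `n_promoters` by resampling when sizes differ).
#' @param windows_per_promoter Background windows per promoter (default 40).
#' @param window_lambda_mean Mean of the exponential law for per-window base
#'   rates (default 0.5).
#' @param independent_observation Draw the observed background independently
#'   of the truth?
#' @return See [assemble_dataset()].
#' @export
simulate_mbd_dataset <- function(n_promoters = 5000L, m_per_group = 3L,
                                 dm_fraction = 0.1, fold_change = 2,
                                 nf = 0, M = 10, sigma = 3,
                                 windows_per_promoter = 40L,
                                 window_lambda_mean = 0.5,
                                 pool = NULL, seed = 1L,
                                 signal_dist = "nb",
                                 noise_model = "poisson",
                                 independent_observation = FALSE) {
  if (is.null(pool)) {
    pool <- build_param_pool(n = n_promoters, seed = child_seed(seed, 1L))
  } else if (nrow(pool) != n_promoters) {
    pool <- withr::with_seed(child_seed(seed, 1L), {
      pool[sample.int(nrow(pool), n_promoters, replace = TRUE), ]
    })
  }
  signal <- simulate_signal(pool, m_per_group, dm_fraction, fold_change,
                            seed = child_seed(seed, 2L),
                            signal_dist = signal_dist)
  n_win <- n_promoters * windows_per_promoter
  lam <- withr::with_seed(child_seed(seed, 3L), {
    rexp(n_win, rate = 1 / window_lambda_mean)
  })
  noise_a <- simulate_window_noise(n_win, m_per_group, lam, nf, M, sigma,
                                   seed = child_seed(seed, 4L),
                                   noise_model = noise_model)
  noise_b <- simulate_window_noise(n_win, m_per_group, lam, nf, M, sigma,
                                   seed = child_seed(seed, 5L),
                                   noise_model = noise_model)
  ob_a <- ob_b <- NULL
  if (independent_observation) {
    ob_a <- simulate_window_noise(n_win, m_per_group, lam, nf, M, sigma,
                                  seed = child_seed(seed, 6L),
                                  noise_model = noise_model)
    ob_b <- simulate_window_noise(n_win, m_per_group, lam, nf, M, sigma,
                                  seed = child_seed(seed, 7L),
                                  noise_model = noise_model)
  }
  assemble_dataset(signal, noise_a, noise_b, windows_per_promoter, ob_a, ob_b)
}
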