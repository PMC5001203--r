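# Benchmark metrics over repeated simulations.

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen DM promoter receives a smaller
#' p-value than a randomly chosen non-DM promoter (ties counted 1/2 via
#' midranks) - the area under the ROC curve for the ranking by p-value.
#'
#' @param p_values Numeric vector of p-values (smaller = more significant).
#' @param labels Logical vector: TRUE for truly DM promoters.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(p_values, labels) {
  stopifnot(length(p_values) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) abort("need both DM and non-DM labels")
  r <- rank(-p_values)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' False-discovery curve
#'
#' The cumulative number of non-DM promoters among the top `k` promoters
#' ranked by p-value, for `k = 1..max_rank`. Ties are broken by promoter id
#' (deterministic).
#'
#' @inheritParams roc_auc
#' @param ids Promoter ids used for the deterministic tie-break (default:
#'   position).
#' @param max_rank Largest rank to report (default: all).
#' @return Integer vector of length `max_rank`, non-decreasing.
#' @export
false_discovery_curve <- function(p_values, labels, ids = seq_along(p_values),
                                  max_rank = length(p_values)) {
  stopifnot(max_rank <= length(p_values))
  ord <- order(p_values, ids)
  cumsum(!as.logical(labels)[ord])[seq_len(max_rank)]
}

#' Statistical power at a p-value cutoff
#'
#' Fraction of truly DM promoters with `p < alpha` (strict).
#'
#' @inheritParams roc_auc
#' @param alpha Cutoff (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
power_at <- function(p_values, labels, alpha = 0.05) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L) abort("need at least one DM label")
  mean(p_values[labels] < alpha)
}

#' False discovery rate at a p-value cutoff
#'
#' Among promoters with `p < alpha`, the fraction that are not DM; defined as
#' 0 when there are no discoveries (flagged via attribute `no_discoveries`).
#'
#' @inheritParams power_at
#' @return FDR in `[0, 1]`.
#' @export
fdr_at <- function(p_values, labels, alpha = 0.05) {
  labels <- as.logical(labels)
  disc <- p_values < alpha
  if (!any(disc)) {
    out <- 0
    attr(out, "no_discoveries") <- TRUE
    return(out)
  }
  mean(!labels[disc])
}

#' The standard simulation scenario grid
#'
#' Replicates 3 or 6 per group, 10% or 30% DM promoters, fold change 2 or 3,
#' noise factor 0, 7 or 20.
#'
#' @return A tibble with columns `m_per_group`, `dm_fraction`, `fold_change`,
#'   `nf`.
#' @export
scenario_grid <- function() {
  tidyr::expand_grid(
    m_per_group = c(3L, 6L),
    dm_fraction = c(0.10, 0.30),
    fold_change = c(2, 3),
    nf = c(0, 7, 20)
  )
}

#' Run the simulation benchmark
#'
#' For every scenario row and repeat: simulate a dataset, run the DM test,
#' and record AUC, false discoveries among the top `top_rank`, power and FDR
#' at `alpha`, plus the same metrics restricted to highly (above the 75%
#' quantile of true methylation level) and weakly (below the 25% quantile)
#' methylated promoters. Scenarios with `fold_change = 1` (null) record the
#' empirical type-I error and the Kolmogorov-Smirnov distance of the
#' p-values from U(0,1) instead of AUC/power/FDR.
#'
#' @param scenarios Scenario tibble (see [scenario_grid()]); extra columns
#'   `n_promoters`, `M`, `sigma` etc. are passed to
#'   [simulate_mbd_dataset()] when present.
#' @param repeats Repeats per scenario (default 20; the full protocol uses
#'   100).
#' @param seed Master seed; every (scenario, repeat) derives its own child
#'   seed, so results are fully reproducible.
#' @param n_promoters Promoters per dataset (default 5000).
#' @param top_rank Rank depth of the false-discovery count (default 500).
#' @param alpha Cutoff for power/FDR/type-I error (default 0.05).
#' @param pool Optional shared parameter pool.
#' @param mle_threshold Passed to [run_dm()].
#' @return An object of class `mbd_benchmark`: list with `metrics` (tibble,
#'   one row per scenario x repeat) and `summary` (per-scenario means and
#'   Monte-Carlo standard errors).
#' @export
run_benchmark <- function(scenarios, repeats = 20L, seed = 1L,
                          n_promoters = 5000L, top_rank = 500L,
                          alpha = 0.05, pool = NULL, mle_threshold = 5L) {
  scenarios <- tibble::as_tibble(scenarios)
  rows <- purrr::map(seq_len(nrow(scenarios)), function(si) {
    sc <- scenarios[si, ]
    purrr::map(seq_len(repeats), function(ri) {
      res <- tryCatch(
        benchmark_one(sc, n_promoters = if ("n_promoters" %in% names(sc))
                        sc$n_promoters else n_promoters,
                      top_rank = top_rank, alpha = alpha, pool = pool,
                      mle_threshold = mle_threshold,
                      seed = child_seed(seed, si, ri)),
        error = function(e) {
          warn(sprintf("scenario %d repeat %d failed: %s", si, ri,
                       conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble::tibble(scenario = si, repeat_id = ri),
                       sc, res)
    })
  })
  metrics <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  mc_se <- function(x) sd(x) / sqrt(sum(is.finite(x)))
  summary <- metrics |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("scenario", "m_per_group", "dm_fraction", "fold_change", "nf")))) |>
    dplyr::summarise(dplyr::across(
      dplyr::where(is.numeric) & !dplyr::any_of("repeat_id"),
      list(mean = ~mean(.x, na.rm = TRUE), se = ~mc_se(.x)),
      .names = "{.col}_{.fn}"), .groups = "drop")
  structure(list(metrics = metrics, summary = summary,
                 repeats = repeats, alpha = alpha, top_rank = top_rank),
            class = "mbd_benchmark")
}

benchmark_one <- function(sc, n_promoters, top_rank, alpha, pool,
                          mle_threshold, seed) {
  g <- function(nm, default) if (nm %in% names(sc)) sc[[nm]] else default
  sim <- simulate_mbd_dataset(
    n_promoters = n_promoters,
    m_per_group = g("m_per_group", 3L),
    dm_fraction = g("dm_fraction", 0.1),
    fold_change = g("fold_change", 2),
    nf = g("nf", 0),
    M = g("M", 10), sigma = g("sigma", 3),
    windows_per_promoter = g("windows_per_promoter", 40L),
    window_lambda_mean = g("window_lambda_mean", 0.5),
    pool = pool, seed = seed,
    signal_dist = g("signal_dist", "nb"),
    noise_model = g("noise_model", "poisson")
  )
  res <- run_dm(sim$promoter_counts, sim$background_counts, sim$conditions,
                mle_threshold = mle_threshold)
  truth <- sim$truth[match(res$promoter_id, sim$truth$promoter_id), ]
  p <- res$p_value
  lab <- truth$dm
  null_scenario <- !any(lab)
  hi <- truth$mean > quantile(truth$mean, 0.75)
  lo <- truth$mean < quantile(truth$mean, 0.25)
  strat <- function(sel) {
    if (null_scenario || sum(lab[sel]) == 0L || sum(!lab[sel]) == 0L) {
      return(c(auc = NA_real_, power = NA_real_))
    }
    c(auc = roc_auc(p[sel], lab[sel]),
      power = power_at(p[sel], lab[sel], alpha))
  }
  s_hi <- strat(hi); s_lo <- strat(lo)
  tibble::tibble(
    auc = if (null_scenario) NA_real_ else roc_auc(p, lab),
    fd_top = if (null_scenario) NA_real_ else {
      as.numeric(false_discovery_curve(p, lab, res$promoter_id,
                                       min(top_rank, length(p)))[
        min(top_rank, length(p))])
    },
    power = if (null_scenario) NA_real_ else power_at(p, lab, alpha),
    fdr = if (null_scenario) NA_real_ else as.numeric(fdr_at(p, lab, alpha)),
    type_i = mean(p[!lab] < alpha),
    ks = as.numeric(suppressWarnings(
      ks.test(p[!lab], "punif")$statistic)),
    auc_high = s_hi[["auc"]], power_high = s_hi[["power"]],
    auc_low = s_lo[["auc"]], power_low = s_lo[["power"]]
  )
}

#' @export
print.mbd_benchmark <- function(x, ...) {
  cat(sprintf("MBDCap-seq simulation benchmark: %d scenario(s) x %d repeat(s)\n\n",
              length(unique(x$metrics$scenario)), x$repeats))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.mbd_benchmark <- function(x, ...) x$metrics

#' @export
glance.mbd_benchmark <- function(x, ...) x$summary

#' @export
autoplot.mbd_benchmark <- function(object, metric = "auc", ...) {
  col <- paste0(metric, "_mean")
  se <- paste0(metric, "_se")
  df <- object$summary
  if (!col %in% names(df)) abort(sprintf("metric '%s' not in summary", metric))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$nf), y = .data[[col]],
                                   group = factor(.data$m_per_group),
                                   colour = factor(.data$m_per_group))) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[col]] - .data[[se]],
                                        ymax = .data[[col]] + .data[[se]]),
                           width = 0.1) +
    ggplot2::labs(x = "noise factor (NF)", y = metric,
                  colour = "replicates/group") +
    ggplot2::theme_minimal()
}
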