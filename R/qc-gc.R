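#' Parse a FastQC per-sequence GC-content table
#'
#' Reads the `>>Per sequence GC content` module from a `fastqc_data.txt` file
#' (tab-separated `#GC Content` / `Count` rows, terminated by `>>END_MODULE`)
#' and returns the normalized GC histogram over the integer bins 0-100.
#'
#' @param path Path to a `fastqc_data.txt`-dialect file.
#' @return A tibble with columns `gc_percent` (0:100) and `density`
#'   (non-negative, summing to 1).
#' @seealso [fit_gc_mixture()], [enrichment_score()]
#' @export
parse_fastqc_gc <- function(path) {
  lines <- readr::read_lines(path)
  start <- grep("^>>Per sequence GC content", lines)
  if (length(start) == 0L) {
    abort("no '>>Per sequence GC content' module found in file")
  }
  start <- start[1L]
  ends <- grep("^>>END_MODULE", lines)
  end <- ends[ends > start][1L]
  if (is.na(end)) abort("'Per sequence GC content' module is not terminated by '>>END_MODULE'")
  body <- lines[(start + 1L):(end - 1L)]
  body <- body[!grepl("^#", body) & nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  gc <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  count <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(gc) || anyNA(count)) abort("malformed rows in the GC content module")
  total <- sum(count)
  if (total <= 0) abort("degenerate GC histogram: all counts are zero")
  dens <- numeric(101L)
  bins <- round(gc)
  keep <- bins >= 0 & bins <= 100
  dens[bins[keep] + 1L] <- dens[bins[keep] + 1L] + count[keep]
  tibble::tibble(gc_percent = 0:100, density = dens / sum(dens))
}

#' Fit a two-component Gaussian mixture to a GC histogram
#'
#' EM on the binned per-read GC distribution,
#' `G = p1 N(mu1, sigma1) + p2 N(mu2, sigma2)` with `p1 + p2 = 1`. Component 1
#' represents ordinary genomic DNA (GC around 40% in human) and component 2
#' the GC-enriched, methylation-captured fraction; after fitting, components
#' are relabelled so that `mu1 <= mu2`.
#'
#' @param hist A GC histogram as returned by [parse_fastqc_gc()] (columns
#'   `gc_percent`, `density`).
#' @param init Optional named list overriding the initial parameters
#'   `mu = c(40, 60)`, `p = c(0.5, 0.5)`, `sigma = c(5, 5)`.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood improves
#'   by less than `tol` or after `max_iter` iterations.
#' @param sigma_floor Lower bound on the component standard deviations (GC
#'   percentage points), preventing singular components on spiky histograms.
#' @return An object of class `gc_mixture_fit`: a list with elements `p1`,
#'   `p2`, `mu1`, `mu2`, `sigma1`, `sigma2`, `es` (the enrichment score),
#'   `loglik`, `converged`, `n_iter`.
#' @examples
#' h <- tibble::tibble(
#'   gc_percent = 0:100,
#'   density = 0.5 * dnorm(0:100, 40, 5) + 0.5 * dnorm(0:100, 60, 5)
#' )
#' h$density <- h$density / sum(h$density)
#' fit <- fit_gc_mixture(h)
#' glance(fit)
#' @export
fit_gc_mixture <- function(hist, init = NULL, max_iter = 500L, tol = 1e-8,
                           sigma_floor = 0.5) {
  stopifnot(is.data.frame(hist), all(c("gc_percent", "density") %in% names(hist)))
  x <- as.numeric(hist$gc_percent)
  w <- as.numeric(hist$density)
  if (any(w < 0) || sum(w) <= 0) abort("histogram densities must be non-negative and sum > 0")
  if (is.unsorted(x, strictly = TRUE)) abort("histogram bins must be strictly increasing")
  if (sum(w > 0) < 20L) abort("need at least 20 non-empty bins to fit the GC mixture")
  w <- w / sum(w)

  p <- init$p %||% c(0.5, 0.5)
  mu <- init$mu %||% c(40, 60)
  sigma <- init$sigma %||% c(5, 5)
  p <- p / sum(p)

  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- p[1] * dnorm(x, mu[1], sigma[1])
    d2 <- p[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    ll <- sum(w[tot > 0] * log(tot[tot > 0]))
    r2 <- ifelse(tot > 0, d2 / tot, 0.5)
    r1 <- 1 - r2
    p <- c(sum(w * r1), sum(w * r2))
    p <- p / sum(p)
    for (k in 1:2) {
      rk <- if (k == 1) r1 else r2
      wk <- w * rk
      sk <- sum(wk)
      if (sk > 1e-12) {
        mu[k] <- sum(wk * x) / sk
        sigma[k] <- sqrt(max(sum(wk * (x - mu[k])^2) / sk, sigma_floor^2))
      }
    }
    if (is.finite(loglik) && ll - loglik < tol) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  if (!converged) {
    warn(sprintf("GC mixture EM did not converge in %d iterations", max_iter))
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sigma <- rev(sigma); p <- rev(p)
  }
  fit <- structure(
    list(p1 = p[1], p2 = p[2], mu1 = mu[1], mu2 = mu[2],
         sigma1 = sigma[1], sigma2 = sigma[2],
         es = NA_real_, loglik = loglik, converged = converged,
         n_iter = iter, hist = tibble::tibble(gc_percent = x, density = w)),
    class = "gc_mixture_fit"
  )
  fit$es <- enrichment_score(fit)
  fit
}

#' GC enrichment score
#'
#' `ES = p2 (mu2 - mu1) / (p1 * 20)`: the mass of the GC-enriched mixture
#' component times its shift from the genomic component, normalized by the
#' non-enriched mass and a 20-point GC scale. At the default human setting
#' (half the reads enriched, means 40 and 60) `ES = 1`.
#'
#' @param fit A `gc_mixture_fit`, or `NULL` when the parameters are supplied
#'   directly.
#' @param p1,p2 Mixture weights (`p1 > 0`).
#' @param mu1,mu2 Component means in GC %.
#' @return The enrichment score, a dimensionless non-negative number when
#'   `mu2 >= mu1`.
#' @examples
#' enrichment_score(p1 = 0.5, p2 = 0.5, mu1 = 40, mu2 = 60)  # 1
#' enrichment_score(p1 = 0.8, p2 = 0.2, mu1 = 40, mu2 = 60)  # 0.25
#' @export
enrichment_score <- function(fit = NULL, p1 = NULL, p2 = NULL,
                             mu1 = NULL, mu2 = NULL) {
  if (!is.null(fit)) {
    if (!inherits(fit, "gc_mixture_fit")) abort("`fit` must be a gc_mixture_fit")
    p1 <- fit$p1; p2 <- fit$p2; mu1 <- fit$mu1; mu2 <- fit$mu2
  }
  if (is.null(p1) || is.null(p2) || is.null(mu1) || is.null(mu2)) {
    abort("supply either `fit` or all of p1, p2, mu1, mu2")
  }
  if (p1 <= 0) abort("enrichment score is undefined for p1 = 0")
  p2 * (mu2 - mu1) / (p1 * 20)
}

#' Sample-acceptance gate on the enrichment score
#'
#' Samples whose GC enrichment score does not exceed the threshold show no
#' evidence of successful methyl-CpG capture and are excluded from analysis.
#' The comparison is strict: `es` exactly at the threshold fails.
#'
#' @param es Enrichment score (finite numeric).
#' @param threshold Acceptance threshold (default 0.2).
#' @return Logical: `TRUE` iff `es > threshold`.
#' @export
qc_pass <- function(es, threshold = 0.2) {
  if (any(!is.finite(es))) abort("`es` must be finite")
  es > threshold
}

#' @export
print.gc_mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian GC mixture\n")
  cat(sprintf("  component 1 (genomic):  p1 = %.4f, mu1 = %.2f, sigma1 = %.2f\n",
              x$p1, x$mu1, x$sigma1))
  cat(sprintf("  component 2 (enriched): p2 = %.4f, mu2 = %.2f, sigma2 = %.2f\n",
              x$p2, x$mu2, x$sigma2))
  cat(sprintf("  enrichment score ES = %.4f (%s at threshold 0.2)\n",
              x$es, if (qc_pass(x$es)) "pass" else "fail"))
  cat(sprintf("  loglik %.6f, %s in %d iterations\n",
              x$loglik, if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @export
tidy.gc_mixture_fit <- function(x, ...) {
  tibble::tibble(
    component = c("genomic", "enriched"),
    p = c(x$p1, x$p2),
    mu = c(x$mu1, x$mu2),
    sigma = c(x$sigma1, x$sigma2)
  )
}

#' @export
glance.gc_mixture_fit <- function(x, ...) {
  tibble::tibble(
    es = x$es, qc_pass = qc_pass(x$es), loglik = x$loglik,
    converged = x$converged, n_iter = x$n_iter
  )
}

#' @export
autoplot.gc_mixture_fit <- function(object, ...) {
  h <- object$hist
  xx <- seq(0, 100, by = 0.25)
  dens <- tibble::tibble(
    gc_percent = rep(xx, 3),
    density = c(object$p1 * dnorm(xx, object$mu1, object$sigma1),
                object$p2 * dnorm(xx, object$mu2, object$sigma2),
                object$p1 * dnorm(xx, object$mu1, object$sigma1) +
                  object$p2 * dnorm(xx, object$mu2, object$sigma2)),
    curve = rep(c("genomic", "enriched", "mixture"), each = length(xx))
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$gc_percent)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density), fill = "grey80") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, colour = .data$curve)) +
    ggplot2::labs(x = "GC content (%)", y = "density",
                  title = sprintf("GC enrichment score = %.2f", object$es)) +
    ggplot2::theme_minimal()
}
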