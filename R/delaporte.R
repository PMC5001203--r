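#' The Delaporte distribution
#'
#' Density and random generation for the Delaporte distribution, the law of
#' `S + B` where `S ~ NegBinomial(size = alpha, prob = 1/(1 + beta))` and
#' `B ~ Poisson(lambda)` are independent. In the MBDCap-seq model the observed
#' promoter count is such a convolution of the true methylation signal (NB)
#' and non-specific background pull-down (Poisson).
#'
#' The mass function at `k` is
#' \deqn{\sum_{j=0}^{k} \frac{\Gamma(\alpha+j)\,\beta^j}{\Gamma(\alpha)\,j!\,
#'   (1+\beta)^{\alpha+j}} \cdot \frac{\lambda^{k-j} e^{-\lambda}}{(k-j)!}}
#' evaluated in log space. `beta = 0` reduces to Poisson(`lambda`);
#' `lambda = 0` reduces to the negative binomial itself.
#'
#' @param x Vector of non-negative integer quantiles.
#' @param n Number of random draws.
#' @param alpha Gamma-mixing shape (> 0); equals the NB size parameter `r`.
#' @param beta Gamma-mixing scale (>= 0); the NB success probability is
#'   `p = 1/(beta + 1)`.
#' @param lambda Poisson mean (>= 0).
#' @param log Return log-density?
#' @return `ddelap()` a numeric vector of (log-)probabilities; `rdelap()` an
#'   integer vector of draws.
#' @examples
#' ddelap(0, alpha = 1, beta = 1, lambda = 1)  # exp(-1)/2
#' sum(ddelap(0:100, 2, 1.5, 3))               # ~1
#' @export
ddelap <- function(x, alpha, beta, lambda, log = FALSE) {
  check_delap_params(alpha, beta, lambda)
  out <- vapply(x, ddelap_log_one, numeric(1),
                alpha = alpha, beta = beta, lambda = lambda)
  if (log) out else exp(out)
}

#' @rdname ddelap
#' @export
rdelap <- function(n, alpha, beta, lambda) {
  check_delap_params(alpha, beta, lambda)
  s <- if (beta > 0) rnbinom(n, size = alpha, prob = 1 / (1 + beta)) else integer(n)
  s + rpois(n, lambda)
}

check_delap_params <- function(alpha, beta, lambda) {
  if (!is.finite(alpha) || alpha <= 0) abort("`alpha` must be finite and > 0")
  if (!is.finite(beta) || beta < 0) abort("`beta` must be finite and >= 0")
  if (!is.finite(lambda) || lambda < 0) abort("`lambda` must be finite and >= 0")
  invisible(TRUE)
}

# Scalar log-pmf. The summand over j (NB mass at j times Poisson mass at
# k - j) is log-concave in j. For large k the sum is confined to the window
# where the Poisson factor carries mass; when that window provably holds the
# mode (its edge terms sit far below its maximum), nothing else contributes.
# Otherwise a coarse scan locates the dominant summand (the NB component can
# decay faster than the Poisson tail) and an ample window around it is added.
ddelap_log_one <- function(k, alpha, beta, lambda) {
  if (is.na(k) || k < 0 || k != floor(k)) return(-Inf)
  if (beta == 0) return(dpois(k, lambda, log = TRUE))
  if (lambda == 0) return(dnbinom(k, size = alpha, prob = 1 / (1 + beta), log = TRUE))
  delap_inner(k, alpha, beta, lambda)$lp
}

# Shared inner-sum machinery; `grad = TRUE` adds the summand-weighted score
# components used by the joint MLE (derivatives w.r.t. alpha, beta, lambda).
delap_inner <- function(k, alpha, beta, lambda, grad = FALSE) {
  k <- as.integer(k)
  p <- 1 / (1 + beta)
  js <- NULL
  terms <- NULL
  if (k <= 512L) {
    js <- 0:k
  } else {
    po_lo <- as.integer(floor(pois_lo_bound(lambda, 46))) - 4L
    po_hi <- as.integer(ceiling(pois_hi_bound(lambda, 46))) + 4L
    lo1 <- max(0L, k - po_hi)
    hi1 <- min(k, k - max(po_lo, 0L))
    if (hi1 >= lo1) {
      cand <- lo1:hi1
      tcand <- dnbinom(cand, size = alpha, prob = p, log = TRUE) +
        dpois(k - cand, lambda, log = TRUE)
      mx <- max(tcand)
      if (is.finite(mx) &&
          (lo1 == 0L || tcand[1L] < mx - 34) &&
          (hi1 == k || tcand[length(tcand)] < mx - 34)) {
        js <- cand
        terms <- tcand
      }
    }
    if (is.null(js)) {
      coarse <- unique(as.integer(round(seq(0, k, length.out = 128L))))
      f <- dnbinom(coarse, size = alpha, prob = p, log = TRUE) +
        dpois(k - coarse, lambda, log = TRUE)
      j0 <- coarse[which.max(f)]
      w <- as.integer(ceiling(k / 127 + 9 * sqrt(lambda) +
                                9 * sqrt(k - j0 + 1))) + 32L
      lo2 <- max(0L, j0 - w)
      hi2 <- min(k, j0 + w)
      if (hi1 < lo1) {
        js <- lo2:hi2
      } else if (lo2 >= lo1 && hi2 <= hi1) {
        js <- lo1:hi1
      } else if (hi2 < lo1 - 1L || lo2 > hi1 + 1L) {
        js <- c(lo1:hi1, lo2:hi2)
      } else {
        js <- min(lo1, lo2):max(hi1, hi2)
      }
    }
  }
  if (is.null(terms)) {
    terms <- dnbinom(js, size = alpha, prob = p, log = TRUE) +
      dpois(k - js, lambda, log = TRUE)
  }
  lp <- logsumexp(terms)
  if (!grad) return(list(lp = lp))
  w <- exp(terms - lp)
  list(
    lp = lp,
    da = sum(w * (digamma(alpha + js) - digamma(alpha) - log1p(beta))),
    db = sum(w * (js / beta - (alpha + js) / (1 + beta))),
    dl = sum(w * ((k - js) / lambda - 1))
  )
}

# Chernoff-style Poisson tail bounds: closed forms guaranteeing tail mass
# < exp(-c), far cheaper than extreme-tail quantile inversion and only
# slightly wider.
pois_hi_bound <- function(lambda, c) lambda + c / 3 + sqrt(c^2 / 9 + 2 * c * lambda)
pois_lo_bound <- function(lambda, c) max(0, lambda - sqrt(2 * c * lambda))

# Effective support of a Delaporte distribution (and of its two component
# factors) at tail mass ~`tail`. The NB component is bounded through its
# Gamma-Poisson mixture representation (Gamma quantile, then the Poisson
# bound at that rate), avoiding qnbinom's slow deep-tail search.
delap_support <- function(alpha, beta, lambda, kmax = Inf, tail = 1e-16) {
  cc <- -log(tail) + 2
  if (beta == 0) {
    nb_lo <- nb_hi <- 0L
  } else {
    g_lo <- qgamma(tail, shape = alpha, scale = beta)
    g_hi <- qgamma(tail, shape = alpha, scale = beta, lower.tail = FALSE)
    nb_lo <- max(0L, as.integer(floor(pois_lo_bound(g_lo, cc))) - 2L)
    nb_hi <- as.integer(ceiling(pois_hi_bound(g_hi, cc))) + 2L
    if (is.finite(kmax)) nb_hi <- min(nb_hi, as.integer(kmax))
    if (nb_hi < nb_lo) nb_lo <- nb_hi
  }
  if (lambda == 0) {
    po_lo <- po_hi <- 0L
  } else {
    po_lo <- max(0L, as.integer(floor(pois_lo_bound(lambda, cc))) - 2L)
    po_hi <- as.integer(ceiling(pois_hi_bound(lambda, cc))) + 2L
    if (is.finite(kmax)) po_hi <- min(po_hi, as.integer(kmax))
    if (po_hi < po_lo) po_lo <- po_hi
  }
  list(lo = nb_lo + po_lo,
       hi = min(nb_hi + po_hi, if (is.finite(kmax)) as.integer(kmax) else nb_hi + po_hi),
       nb_lo = nb_lo, nb_hi = nb_hi, po_lo = po_lo, po_hi = po_hi,
       w_nb = nb_hi - nb_lo + 1L, w_po = po_hi - po_lo + 1L)
}

# Banded pmf vector via truncated component convolution (direct shift-add
# over the shorter factor, or padded FFT). Exact per-element relative
# accuracy on the direct path; FFT keeps absolute accuracy ~1e-13 of the
# peak. Used where a factor is narrow; wide-band callers use the strided
# characteristic-function route instead.
delap_pmf_band <- function(alpha, beta, lambda, kmax = Inf, tail = 1e-16) {
  s <- delap_support(alpha, beta, lambda, kmax, tail)
  nb <- if (beta == 0) 1 else {
    nb_pmf_range(s$nb_lo, s$nb_hi, alpha, 1 / (1 + beta))
  }
  po <- if (lambda == 0) 1 else pois_pmf_range(s$po_lo, s$po_hi, lambda)
  exact <- min(length(nb), length(po)) <= 256L
  pmf <- pmax(conv_open(nb, po), 0)
  offset <- s$nb_lo + s$po_lo
  if (is.finite(kmax) && offset + length(pmf) - 1L > kmax) {
    keep <- as.integer(kmax) - offset + 1L
    if (keep < 1L) {
      offset <- as.integer(kmax); pmf <- 0
    } else {
      pmf <- pmf[seq_len(keep)]
    }
  }
  attr(pmf, "exact") <- exact
  list(offset = as.integer(offset), pmf = pmf)
}

# Bin masses sum_{r=0}^{G-1} p(anchor + G*j + r) for j = 0..n_out-1,
# synthesized from the closed-form characteristic functions of the NB and
# Poisson components times the G-boxcar factor, sampled at M centred
# (wrapped) frequencies 2*pi*m/(M*G) and inverted with one M-point FFT.
# Binning is what makes stride-G sampling alias-free here: the boxcar-
# smoothed sequence has its spectrum concentrated at |omega| << pi/G when
# the distribution's sd is much larger than G, so the discarded frequency
# bands carry ~exp(-(pi*sd/G)^2/2) of the content. With G = 1 this is a
# dense pmf evaluation. M*G must cover the whole support in one period;
# mass below the anchor wraps to the top of the window, so M also covers
# the anchor-to-support-floor distance on top of n_out.
delap_bin_masses <- function(alpha, beta, lambda, anchor, G, n_out, support) {
  j_above <- max(0, ceiling((support$hi - anchor) / G))
  j_below <- max(0, ceiling((anchor - support$lo) / G))
  M <- bitwShiftL(1L, max(1L, ceiling(log2(
    max(j_above, n_out) + j_below + 8L
  ))))
  m <- 0:(M - 1L)
  m <- m - M * (m > M %/% 2L)
  om <- 2 * pi * m / (M * G)
  co <- cos(om); si <- sin(om)
  lre <- numeric(M); lim <- numeric(M)          # log characteristic function
  if (beta > 0) {
    q <- beta / (1 + beta)
    zr <- 1 - q * co; zi <- -q * si
    lre <- lre - alpha * (0.5 * log(zr * zr + zi * zi) + log1p(beta))
    lim <- lim - alpha * atan2(zi, zr)
  }
  if (lambda > 0) {
    lre <- lre + lambda * (co - 1)
    lim <- lim + lambda * si
  }
  lim <- lim - om * anchor
  mag <- exp(lre)
  f_r <- mag * cos(lim); f_i <- mag * sin(lim)
  if (G > 1L) {
    # boxcar factor (1 - e^{-i om G}) / (1 - e^{-i om}); equals G at om = 0
    bg_r <- 1 - cos(om * G); bg_i <- sin(om * G)
    d <- (1 - co)^2 + si^2
    box_r <- (bg_r * (1 - co) + bg_i * si) / d
    box_i <- (bg_i * (1 - co) - bg_r * si) / d
    box_r[1L] <- G; box_i[1L] <- 0
    tmp <- f_r * box_r - f_i * box_i
    f_i <- f_r * box_i + f_i * box_r
    f_r <- tmp
  }
  vals <- Re(stats::fft(complex(real = f_r, imaginary = f_i))) / (M * G)
  pmax(vals[seq_len(n_out)], 0)
}

# Contiguous pmf ranges by the one-step recurrence (one density call plus a
# cumulative product), which is much cheaper than element-wise density calls
# over the wide bands that pooled counts require. Values stay within double
# range because the band edges carry >= `tail` relative mass.
nb_pmf_range <- function(k0, k1, size, prob) {
  if (k1 <= k0 + 1024L) return(dnbinom(k0:k1, size = size, prob = prob))
  ks <- (k0 + 1L):k1
  ratios <- (size + ks - 1) / ks * (1 - prob)
  c(1, cumprod(ratios)) * dnbinom(k0, size = size, prob = prob)
}

pois_pmf_range <- function(k0, k1, lambda) {
  if (k1 <= k0 + 1024L) return(dpois(k0:k1, lambda))
  ks <- (k0 + 1L):k1
  c(1, cumprod(lambda / ks)) * dpois(k0, lambda)
}

# Open (full) convolution of two non-negative vectors. The direct shift-add
# path keeps per-element relative accuracy (sums of positive terms), which the
# FFT path cannot guarantee deep in the tails; it is used whenever the shorter
# factor is small enough to loop over.
conv_open <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(b * a)
  if (min(length(a), length(b)) <= 256L) {
    if (length(b) > length(a)) { tmp <- a; a <- b; b <- tmp }
    out <- numeric(length(a) + length(b) - 1L)
    la <- length(a)
    for (i in seq_along(b)) {
      idx <- i:(i + la - 1L)
      out[idx] <- out[idx] + b[i] * a
    }
    out
  } else {
    # zero-pad to a highly composite length: mixed-radix FFTs on awkward
    # (e.g. prime) lengths degrade to quadratic time
    n_out <- length(a) + length(b) - 1L
    nfft <- bitwShiftL(1L, ceiling(log2(n_out)))
    fa <- stats::fft(c(a, numeric(nfft - length(a))))
    fb <- stats::fft(c(b, numeric(nfft - length(b))))
    Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n_out)] / nfft
  }
}
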