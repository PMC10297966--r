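#' Telomere length distribution (lognormal body + heavy lognormal tail)
#'
#' Lengths are drawn from a two-component mixture: with probability
#' `tail_weight` a lognormal "super-long" tail (median `tail_median_kb`,
#' log-sd `tail_sigma`), otherwise a lognormal body. The body is recentred
#' as the tail weight grows so that the mixture mean always equals
#' `body_mean_kb` and the body coefficient of variation stays at
#' `body_sd_kb / body_mean_kb`; the mixture standard deviation is emergent.
#'
#' @param body_mean_kb,body_sd_kb target mean and body sd in kb (both > 0).
#' @param tail_weight mixture weight of the tail component, in [0, 1).
#' @param tail_median_kb,tail_sigma lognormal tail parameters.
#' @param max_kb optional hard upper truncation in kb (draws above are
#'   rejected); use when the emulated sample demonstrably contains no
#'   lengths beyond a bound.
#' @return an object of class `telomap_lengthdist`.
#' @export
length_distribution <- function(body_mean_kb, body_sd_kb, tail_weight = 0,
                                tail_median_kb = 20, tail_sigma = 0.6,
                                max_kb = Inf) {
  if (body_mean_kb <= 0 || body_sd_kb <= 0)
    stop("body mean and sd must be positive", call. = FALSE)
  if (tail_weight < 0 || tail_weight >= 1)
    stop("tail_weight must be in [0, 1)", call. = FALSE)
  if (max_kb <= body_mean_kb)
    stop("max_kb must exceed the mean", call. = FALSE)
  d <- structure(
    list(body_mean_kb = body_mean_kb, body_sd_kb = body_sd_kb,
         tail_weight = tail_weight, tail_median_kb = tail_median_kb,
         tail_sigma = tail_sigma, max_kb = max_kb),
    class = "telomap_lengthdist")
  dist_components(d)   # errors early if the tail weight is infeasible
  d
}

# moment-matched lognormal parameters for mean m, sd s
lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# resolved component parameters after recentring the body
dist_components <- function(d) {
  tail_mean <- d$tail_median_kb * exp(d$tail_sigma^2 / 2)
  body_mean <- (d$body_mean_kb - d$tail_weight * tail_mean) /
    (1 - d$tail_weight)
  if (body_mean <= 0)
    stop("tail_weight too large: recentred body mean would be non-positive",
         call. = FALSE)
  body_sd <- d$body_sd_kb * body_mean / d$body_mean_kb
  body <- lnorm_params(body_mean, body_sd)
  list(body_meanlog = body$meanlog, body_sdlog = body$sdlog,
       tail_meanlog = log(d$tail_median_kb), tail_sdlog = d$tail_sigma,
       tail_mean = tail_mean, body_mean = body_mean, body_sd = body_sd)
}

#' Mean of a length distribution (exact, by construction)
#' @param d a `telomap_lengthdist`.
#' @return mean length in kb.
#' @export
dist_mean_kb <- function(d) d$body_mean_kb

#' Analytic exceedance probability P(length > x)
#' @param d a `telomap_lengthdist`.
#' @param x_kb threshold in kb.
#' @return probability that a draw exceeds `x_kb` (conditional on the
#'   truncation bound when `max_kb` is finite).
#' @export
dist_p_exceed <- function(d, x_kb) {
  cp <- dist_components(d)
  raw <- function(x) {
    (1 - d$tail_weight) *
      plnorm(x, cp$body_meanlog, cp$body_sdlog, lower.tail = FALSE) +
      d$tail_weight *
      plnorm(x, cp$tail_meanlog, cp$tail_sdlog, lower.tail = FALSE)
  }
  mx <- d$max_kb
  if (!is.null(mx) && is.finite(mx)) {
    if (x_kb >= mx) return(0)
    return((raw(x_kb) - raw(mx)) / (1 - raw(mx)))
  }
  raw(x_kb)
}

#' Sample telomere lengths
#'
#' Draws are optionally conditioned on exceeding `min_kb` (the assay's
#' detection floor): a reported length distribution describes detected
#' telomeres, so sub-floor draws are resampled.
#'
#' @param d a `telomap_lengthdist`.
#' @param n number of draws.
#' @param min_kb lower truncation in kb (0 disables).
#' @return numeric vector of lengths in kb.
#' @export
sample_lengths <- function(d, n, min_kb = 0) {
  if (n == 0) return(numeric(0))
  cp <- dist_components(d)
  draw <- function(m) {
    tail <- runif(m) < d$tail_weight
    out <- numeric(m)
    out[tail] <- exp(rnorm(sum(tail), cp$tail_meanlog, cp$tail_sdlog))
    out[!tail] <- exp(rnorm(sum(!tail), cp$body_meanlog, cp$body_sdlog))
    out
  }
  mx <- if (is.null(d$max_kb)) Inf else d$max_kb
  out <- draw(n)
  for (i in 1:50) {
    bad <- out < min_kb | out > mx
    if (!any(bad)) break
    out[bad] <- draw(sum(bad))
  }
  out
}

#' Calibrate the super-long tail mass of a length distribution
#'
#' Finds, by monotone bisection on `tail_weight`, the distribution whose
#' analytic P(length > `threshold_kb`) equals `target` within `tol`. If the
#' body alone already carries at least the target mass the tail weight is 0
#' (a tail cannot remove body mass).
#'
#' @param d a `telomap_lengthdist` (its tail_weight is ignored).
#' @param target target exceedance probability, in [0, 0.5].
#' @param threshold_kb super-long threshold (default 15 kb).
#' @param tol tolerance on the probability.
#' @return a recalibrated `telomap_lengthdist`.
#' @export
calibrate_tail <- function(d, target, threshold_kb = 15, tol = 1e-3) {
  if (target < 0 || target > 0.5)
    stop("target must be in [0, 0.5]", call. = FALSE)
  at_w <- function(w) {
    dd <- d; dd$tail_weight <- w
    dist_p_exceed(dd, threshold_kb)
  }
  if (target == 0 || at_w(0) >= target) {
    d$tail_weight <- 0
    return(d)
  }
  tail_mean <- d$tail_median_kb * exp(d$tail_sigma^2 / 2)
  hi <- min(0.9, 0.95 * d$body_mean_kb / tail_mean)
  if (at_w(hi) < target)
    stop("calibration failure: target tail mass unreachable with the given ",
         "tail parameters", call. = FALSE)
  lo <- 0
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (at_w(mid) < target) lo <- mid else hi <- mid
    if (abs(at_w(mid) - target) < tol / 10) break
  }
  d$tail_weight <- (lo + hi) / 2
  if (abs(at_w(d$tail_weight) - target) > tol)
    stop("calibration failure: bisection did not converge", call. = FALSE)
  d
}

#' @export
print.telomap_lengthdist <- function(x, ...) {
  cat(sprintf(
    "<telomap_lengthdist: mean %.2f kb (body sd %.2f), tail w=%.4f @ median %.1f kb>\n",
    x$body_mean_kb, x$body_sd_kb, x$tail_weight, x$tail_median_kb))
  invisible(x)
}
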