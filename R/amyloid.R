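#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Models the bimodal distribution of CSF amyloid-beta 1-42 as a mixture of an
#' amyloid-abnormal (lower mean) and amyloid-normal (higher mean) Gaussian.
#' Components are canonicalised so that `means[1] < means[2]`.
#'
#' Initialisation splits the data at its median and uses the 25th/75th
#' percentiles as starting means, which makes the fit deterministic for a
#' given data vector; `seed` is accepted for interface stability but the
#' default initialisation draws no random numbers.
#'
#' @param values numeric vector (at least 10 finite values, positive variance).
#' @param seed integer, reserved for randomised restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return An object of class `gmm_fit`: `means`, `sds`, `weights`, `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(60, 190, 40), rnorm(40, 343, 50))
#' fit_gmm_1d(x)
#' @export
fit_gmm_1d <- function(values, seed = 1L, tol = 1e-8, max_iter = 500L) {
  x <- values[is.finite(values)]
  if (length(x) < 10) stop("need at least 10 finite values")
  if (stats::var(x) == 0) stop("degenerate input: zero variance")

  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sd0 <- rep(stats::sd(x) / 2, 2)
  w <- c(0.5, 0.5)
  n <- length(x)

  loglik_of <- function(mu, sd0, w) {
    d <- cbind(w[1] * stats::dnorm(x, mu[1], sd0[1]),
               w[2] * stats::dnorm(x, mu[2], sd0[2]))
    sum(log(rowSums(d)))
  }

  ll <- loglik_of(mu, sd0, w)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: responsibilities
    d <- cbind(w[1] * stats::dnorm(x, mu[1], sd0[1]),
               w[2] * stats::dnorm(x, mu[2], sd0[2]))
    r <- d / rowSums(d)
    # M-step
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd0 <- sqrt(pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, 1e-12))
    ll_new <- loglik_of(mu, sd0, w)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= tol * (abs(ll) + tol)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  ord <- order(mu)
  structure(list(means = mu[ord], sds = sd0[ord], weights = w[ord] / sum(w),
                 loglik = ll, loglik_trace = trace, n_iter = iter,
                 converged = converged, n = n),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> ", x$n, " values, loglik ", format(x$loglik), ", ",
      x$n_iter, " iterations", if (!x$converged) " (not converged)", "\n",
      sep = "")
  cat(sprintf("  component 1: %.1f (sd %.1f), weight %.3f\n",
              x$means[1], x$sds[1], x$weights[1]))
  cat(sprintf("  component 2: %.1f (sd %.1f), weight %.3f\n",
              x$means[2], x$sds[2], x$weights[2]))
  invisible(x)
}

#' Derive an amyloid positivity cut-point from a mixture fit
#'
#' The cut-point separating the two Gaussians is taken as the `percentile`
#' quantile of one component; by default the 99th percentile of the
#' lower-mean (amyloid-abnormal) component, placing the boundary at the upper
#' tail of the abnormal distribution so that "below cut-point" defines
#' positivity.
#'
#' @param fit a [fit_gmm_1d()] result.
#' @param percentile quantile in (0, 1).
#' @param source_component `"lower_mean"` or `"upper_mean"`.
#' @return An object of class `amyloid_cutpoint` with fields `value`,
#'   `percentile`, `source_component`, `fit`.
#' @examples
#' fit <- structure(list(means = c(190, 343), sds = c(40, 50),
#'                       weights = c(0.55, 0.45), converged = TRUE),
#'                  class = "gmm_fit")
#' derive_cutpoint(fit)$value  # 190 + qnorm(0.99) * 40
#' @export
derive_cutpoint <- function(fit, percentile = 0.99,
                            source_component = c("lower_mean", "upper_mean")) {
  stopifnot(inherits(fit, "gmm_fit"))
  source_component <- match.arg(source_component)
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 1)
    stop("percentile must lie strictly inside (0, 1)")
  if (!isTRUE(fit$converged)) stop("mixture fit did not converge")
  k <- if (source_component == "lower_mean") 1L else 2L
  value <- stats::qnorm(percentile, mean = fit$means[k], sd = fit$sds[k])
  structure(list(value = value, percentile = percentile,
                 source_component = source_component, fit = fit),
            class = "amyloid_cutpoint")
}

#' @export
print.amyloid_cutpoint <- function(x, ...) {
  cat(sprintf("<amyloid_cutpoint> %.2f pg/mL (%.0fth percentile of %s component)\n",
              x$value, 100 * x$percentile, x$source_component))
  invisible(x)
}

#' Classify amyloid status against a cut-point
#'
#' Positive means strictly below the cut-point; a value exactly at the
#' cut-point is classified negative.
#'
#' @param values numeric CSF amyloid values (pg/mL).
#' @param cutpoint an `amyloid_cutpoint` or single numeric value.
#' @return character vector of `"positive"` / `"negative"`.
#' @export
classify_amyloid <- function(values, cutpoint) {
  cut <- .cutpoint_value(cutpoint)
  if (any(!is.finite(values))) stop("non-finite amyloid value")
  ifelse(values < cut, "positive", "negative")
}
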