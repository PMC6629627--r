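#' Steady-state Hill transfer-function parameters
#'
#' The transfer function relating an input dose x (light intensity in
#' umol m-2 s-1, or a chemical inducer concentration) to reporter output
#' is `y = y0 + dy * x^n / (x^n + K^n)`: basal output `y0` at zero input,
#' dynamic span `dy` (so saturating output is `y0 + dy`), Hill coefficient
#' `n` and half-maximum activation dose `K`.
#'
#' All four parameters must be strictly positive: the pooled log-residual
#' fit requires positive model values everywhere.
#'
#' @param y0 basal output (MEFL), > 0.
#' @param dy dynamic span (MEFL), > 0.
#' @param n Hill coefficient, > 0.
#' @param K half-maximum activation dose (input units), > 0.
#' @return list of class `hill_params`.
#' @export
hill_params <- function(y0, dy, n, K) {
  p <- list(y0 = y0, dy = dy, n = n, K = K)
  if (any(!vapply(p, function(v) is.finite(v) && v > 0, logical(1)))) {
    stop("all Hill parameters (y0, dy, n, K) must be finite and > 0", call. = FALSE)
  }
  structure(p, class = "hill_params")
}

assert_hill_params <- function(x) {
  if (!inherits(x, "hill_params")) stop("expected `hill_params`", call. = FALSE)
  invisible(x)
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params: y0=%.4g, dy=%.4g, n=%.4g, K=%.4g>\n",
              x$y0, x$dy, x$n, x$K))
  invisible(x)
}

#' Evaluate the Hill transfer function
#'
#' @param params a [hill_params()].
#' @param x input dose(s), >= 0. `x = 0` returns `y0` exactly.
#' @return Output fluorescence, same length as `x`.
#' @export
hill_eval <- function(params, x) {
  assert_hill_params(params)
  if (any(!is.finite(x)) || any(x < 0)) stop("doses must be finite and >= 0", call. = FALSE)
  out <- rep(params$y0, length(x))
  pos <- x > 0
  if (any(pos)) {
    # compute on log scale to avoid overflow of x^n at extreme doses
    r <- exp(params$n * (log(x[pos]) - log(params$K)))  # (x/K)^n
    out[pos] <- params$y0 + params$dy * r / (r + 1)
  }
  out
}

#' Fit the Hill transfer function by pooled log residuals
#'
#' Pools all replicate points and minimizes the sum of squared differences
#' between log observed fluorescence and log model prediction with the
#' Levenberg-Marquardt algorithm, which weighs low and high fluorescence
#' values evenly across the decades-spanning dynamic range. Parameters are
#' optimized on the log scale internally, enforcing positivity without
#' hard bounds, and reported on the natural scale with delta-method
#' standard errors from the damped-least-squares covariance approximation.
#'
#' Default initial guesses are scale-free: `y0 = min(y)`,
#' `dy = max(y) - min(y)`, `K` = geometric median of the positive doses,
#' `n = 1`.
#'
#' @param data data.frame with columns `x` (dose, >= 0) and `y` (reporter
#'   fluorescence, > 0); an optional `replicate` column is carried along
#'   but the pooled objective ignores labels.
#' @param init optional [hill_params()] starting point.
#' @param max_iter,ftol Levenberg-Marquardt iteration cap and relative
#'   objective-reduction tolerance.
#' @return list of class `fit_result`: `estimates` ([hill_params()]),
#'   `se` (named, natural scale), `residual` (sum of squared log
#'   residuals), `converged`, `iterations`, `message`, `predictions`
#'   (per-point model values).
#' @export
fit_hill <- function(data, init = NULL, max_iter = 1000L, ftol = 1e-10) {
  x <- data$x; y <- data$y
  if (is.null(x) || is.null(y)) stop("`data` needs columns x and y", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("non-finite data points", call. = FALSE)
  if (any(y <= 0)) {
    stop(paste("non-positive fluorescence values cannot enter the log-residual",
               "objective; resolve them (e.g. drop undetected conditions)",
               "before fitting"), call. = FALSE)
  }
  if (length(unique(x)) < 4L) stop("need >= 4 distinct doses for 4 free parameters", call. = FALSE)

  if (is.null(init)) {
    xp <- x[x > 0]
    init <- hill_params(y0 = max(min(y), 1e-12),
                        dy = max(max(y) - min(y), 1e-6 * max(y)),
                        n = 1,
                        K = exp(median(log(xp))))
  } else {
    assert_hill_params(init)
  }
  theta0 <- log(unlist(init[c("y0", "dy", "n", "K")]))
  resid_fn <- function(theta) {
    p <- exp(theta)
    pr <- hill_params(p[1], p[2], p[3], p[4])
    log(y) - log(hill_eval(pr, x))
  }
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = min(max_iter, 1024L),
                              ftol = ftol, ptol = 1e-12, gtol = 0))
  finalize_fit(fit, param_names = c("y0", "dy", "n", "K"),
               n_obs = length(y),
               make_params = function(p) hill_params(p[1], p[2], p[3], p[4]),
               predict_fn = function(params) hill_eval(params, x))
}

# shared LM post-processing: natural-scale estimates, delta-method SEs from
# the J'J covariance approximation, convergence diagnostics
finalize_fit <- function(fit, param_names, n_obs, make_params, predict_fn) {
  theta <- fit$par
  p <- unname(exp(theta))
  params <- make_params(p)
  rss <- sum(fit$fvec^2)
  dof <- max(n_obs - length(theta), 1L)
  se <- rep(NA_real_, length(theta))
  cv <- tryCatch(solve(fit$hessian) * rss / dof, error = function(e) NULL)
  if (!is.null(cv)) {
    d <- diag(cv)
    d[d < 0] <- NA_real_
    se <- sqrt(d) * p  # delta method: se on natural scale
  }
  names(se) <- param_names
  converged <- fit$info %in% 1:4
  structure(list(estimates = params, se = se, residual = rss,
                 converged = converged, iterations = fit$niter,
                 message = fit$message,
                 predictions = predict_fn(params)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  est <- unlist(x$estimates[setdiff(names(x$estimates), "swapped_kg_kd")])
  cat("<fit_result>\n")
  for (nm in names(est)) {
    cat(sprintf("  %-4s %.6g (se %.3g)\n", nm, est[[nm]],
                if (nm %in% names(x$se)) x$se[[nm]] else NA))
  }
  cat(sprintf("  residual (sum sq log): %.6g; %s after %d iterations\n",
              x$residual, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}
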