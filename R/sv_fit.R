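#' Fit a Stern-Volmer quenching model
#'
#' Fits one of the three Stern-Volmer model families to a titration
#' series of fluorescence ratios F0/F against molar quencher
#' concentration \eqn{[Q]}:
#'
#' \describe{
#'   \item{`"linear"`}{\eqn{F_0/F = 1 + K_{SV}[Q]} — a single collisional
#'     (dynamic, \eqn{K_D}) or associative (static, \eqn{K_S}) process.
#'     Which of the two the slope represents cannot be decided from one
#'     isotherm; see [classify_mechanism()].}
#'   \item{`"combined"`}{\eqn{F_0/F = (1 + K_D[Q])(1 + K_S[Q])}, fitted as
#'     the quadratic \eqn{1 + b[Q] + c[Q]^2}; \eqn{K_D} and \eqn{K_S} are
#'     recovered as the (unordered) roots of \eqn{x^2 - bx + c = 0}. When
#'     the discriminant is negative or a root is negative the pair has no
#'     physical solution and `converged` is `FALSE`.}
#'   \item{`"sphere"`}{\eqn{F_0/F = (1 + K_D[Q])\,e^{V[Q]}}, the
#'     sphere-of-action model; \eqn{V} (1/M) is proportional to the volume
#'     around the fluorophore within which quenching occurs with unit
#'     probability. Fitted by bounded Levenberg-Marquardt least squares
#'     with multi-start initialisation.}
#' }
#'
#' All fits constrain the intercept to 1, since F0/F is identically 1 at
#' zero quencher by construction. A free intercept is available for
#' diagnostics via `free_intercept = TRUE` (linear model only). Fits are
#' performed on the replicate-mean ratios, unweighted by default;
#' `weights = "inverse_variance"` uses 1/sd^2 weights where the series
#' carries replicate standard deviations.
#'
#' @param series A [quenching_series()].
#' @param model `"linear"`, `"combined"` or `"sphere"`.
#' @param weights `"none"` (default) or `"inverse_variance"`.
#' @param free_intercept Fit the intercept instead of fixing it at 1
#'   (diagnostic; linear model only).
#' @return An object of class `sv_fit` with elements `model`,
#'   `coefficients` (named: `K_SV`; or `K_lo`/`K_hi`, the unordered
#'   static/dynamic root pair; or `K_D`/`V`), `param_se`, `r_squared`,
#'   `converged`, `reason`, `fitted`, `series`. Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`,
#'   `simulate`.
#' @examples
#' q <- seq(0, 0.9, length.out = 7)
#' s <- quenching_series(q, 1 + 0.444 * q)
#' sv_fit(s, "linear")
#' @export
sv_fit <- function(series, model = c("linear", "combined", "sphere"),
                   weights = c("none", "inverse_variance"),
                   free_intercept = FALSE) {
  stopifnot(inherits(series, "quenching_series"))
  model <- match.arg(model)
  weights <- match.arg(weights)
  q <- series$concentrations
  y <- series$ratio_mean
  w <- NULL
  if (weights == "inverse_variance") {
    if (is.null(series$ratio_sd))
      stop("inverse-variance weighting requires ratio_sd in the series")
    sd <- series$ratio_sd
    sd[sd <= 0] <- min(sd[sd > 0], 1e-6)  # zero-sd baseline point
    w <- 1 / sd^2
  }
  fit <- switch(model,
    linear = fit_sv_linear(q, y, w, free_intercept),
    combined = fit_sv_combined(q, y, w),
    sphere = fit_sv_sphere(q, y, w))
  fit$series <- series
  fit$weights <- weights
  fit$call <- match.call()
  class(fit) <- c(paste0("sv_fit_", model), "sv_fit")
  fit
}

# vcov for lm fits without summary.lm's "essentially perfect fit" warning,
# which is routine when fitting noiseless synthetic validation data.
lm_vcov_quiet <- function(fit) {
  withCallingHandlers(
    stats::vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

fit_sv_linear <- function(q, y, w, free_intercept) {
  if (length(unique(q)) < 3)
    stop("linear Stern-Volmer fit needs at least 3 distinct concentrations")
  if (free_intercept) {
    lmfit <- stats::lm(y ~ q, weights = w)
    co <- stats::coef(lmfit)
    se <- sqrt(diag(lm_vcov_quiet(lmfit)))
    fitted <- as.numeric(stats::fitted(lmfit))
    coefficients <- c(K_SV = unname(co["q"]), intercept = unname(co[1]))
    param_se <- c(K_SV = unname(se["q"]), intercept = unname(se[1]))
  } else {
    z <- y - 1
    lmfit <- stats::lm(z ~ 0 + q, weights = w)
    co <- stats::coef(lmfit)
    se <- sqrt(diag(lm_vcov_quiet(lmfit)))
    fitted <- 1 + as.numeric(stats::fitted(lmfit))
    coefficients <- c(K_SV = unname(co["q"]))
    param_se <- c(K_SV = unname(se["q"]))
  }
  list(model = "linear", coefficients = coefficients, param_se = param_se,
       r_squared = r_squared_or_na(y, fitted), converged = TRUE,
       reason = NULL, fitted = fitted, lm = lmfit)
}

fit_sv_combined <- function(q, y, w) {
  if (length(unique(q)) < 4)
    stop("combined static/dynamic fit needs at least 4 distinct concentrations")
  z <- y - 1
  q2 <- q^2
  lmfit <- stats::lm(z ~ 0 + q + q2, weights = w)
  co <- stats::coef(lmfit)
  se <- sqrt(diag(lm_vcov_quiet(lmfit)))
  b <- unname(co["q"]); cc <- unname(co["q2"])
  fitted <- 1 + as.numeric(stats::fitted(lmfit))
  disc <- b^2 - 4 * cc
  if (disc < 0) {
    roots <- c(NA_real_, NA_real_)
    converged <- FALSE
    reason <- "no real solutions"
  } else {
    r1 <- (b - sqrt(disc)) / 2
    r2 <- (b + sqrt(disc)) / 2
    roots <- c(r1, r2)
    if (any(roots < 0)) {
      converged <- FALSE
      reason <- "no real solutions"  # negative constants are unphysical
    } else {
      converged <- TRUE
      reason <- NULL
    }
  }
  list(model = "combined",
       coefficients = c(K_lo = roots[1], K_hi = roots[2]),
       quad = c(b = b, c = cc),
       param_se = c(b = unname(se["q"]), c = unname(se["q2"])),
       r_squared = r_squared_or_na(y, fitted), converged = converged,
       reason = reason, fitted = fitted, lm = lmfit)
}

fit_sv_sphere <- function(q, y, w) {
  if (length(unique(q)) < 4)
    stop("sphere-of-action fit needs at least 4 distinct concentrations")
  if (is.null(w)) w <- rep(1, length(q))
  # initialise K_D from the through-origin linear slope, V = 0, plus
  # deterministic perturbed restarts
  k0 <- max(sum(q * (y - 1)) / sum(q^2), 0)
  starts <- list(c(K_D = k0, V = 0),
                 c(K_D = 0.5 * k0, V = 0.5 * k0),
                 c(K_D = 2 * k0 + 1, V = 0.1 * k0),
                 c(K_D = 0.1 * k0, V = k0 + 1))
  dat <- data.frame(q = q, y = y)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ (1 + K_D * q) * exp(V * q), data = dat,
                        start = as.list(st), weights = w,
                        lower = c(K_D = 0, V = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(model = "sphere",
                coefficients = c(K_D = NA_real_, V = NA_real_),
                param_se = c(K_D = NA_real_, V = NA_real_),
                r_squared = NA_real_, converged = FALSE,
                reason = "nonlinear least squares did not converge",
                fitted = rep(NA_real_, length(q)), nls = NULL))
  }
  fit <- best$fit
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 2))
  fitted <- as.numeric(stats::fitted(fit))
  list(model = "sphere",
       coefficients = c(K_D = unname(co["K_D"]), V = unname(co["V"])),
       param_se = c(K_D = unname(se[1]), V = unname(se[2])),
       r_squared = r_squared_or_na(y, fitted), converged = TRUE,
       reason = NULL, fitted = fitted, nls = fit)
}

#' @export
coef.sv_fit <- function(object, ...) object$coefficients

#' @export
fitted.sv_fit <- function(object, ...) object$fitted

#' @export
residuals.sv_fit <- function(object, ...)
  object$series$ratio_mean - object$fitted

#' Predict F0/F at new quencher concentrations
#'
#' @param object An `sv_fit`.
#' @param newdata Numeric vector of molar concentrations; defaults to the
#'   fitted series' concentrations.
#' @param ... Unused.
#' @return Predicted F0/F ratios.
#' @export
predict.sv_fit <- function(object, newdata = NULL, ...) {
  q <- if (is.null(newdata)) object$series$concentrations
       else as.numeric(newdata)
  co <- object$coefficients
  switch(object$model,
    linear = {
      icpt <- if ("intercept" %in% names(co)) co[["intercept"]] else 1
      icpt + co[["K_SV"]] * q
    },
    combined = {
      if (!object$converged) {
        b <- object$quad[["b"]]; cc <- object$quad[["c"]]
        1 + b * q + cc * q^2
      } else (1 + co[["K_lo"]] * q) * (1 + co[["K_hi"]] * q)
    },
    sphere = (1 + co[["K_D"]] * q) * exp(co[["V"]] * q))
}

#' @export
print.sv_fit <- function(x, digits = 4, ...) {
  lab <- switch(x$model, linear = "Linear Stern-Volmer",
                combined = "Combined static/dynamic Stern-Volmer",
                sphere = "Sphere-of-action Stern-Volmer")
  cat(lab, "fit\n")
  if (x$model == "combined") {
    if (x$converged)
      cat(sprintf("  quenching constant pair {%.*g, %.*g} 1/M (unordered; assign K_D/K_S with temperature evidence)\n",
                  digits, x$coefficients[["K_lo"]], digits,
                  x$coefficients[["K_hi"]]))
    else
      cat("  ", x$reason, sprintf(" (quadratic b = %.*g, c = %.*g)\n",
          digits, x$quad[["b"]], digits, x$quad[["c"]]))
  } else {
    for (nm in names(x$coefficients))
      cat(sprintf("  %s = %.*g 1/M (se %.*g)\n", nm, digits,
                  x$coefficients[[nm]], digits, x$param_se[[nm]]))
  }
  cat(sprintf("  r^2 = %.3f, converged: %s\n",
              x$r_squared, x$converged))
  invisible(x)
}

#' @export
summary.sv_fit <- function(object, ...) {
  out <- list(model = object$model, coefficients = object$coefficients,
              param_se = object$param_se, r_squared = object$r_squared,
              converged = object$converged, reason = object$reason,
              n = length(object$series$concentrations),
              temperature = object$series$temperature,
              residual_sd = stats::sd(residuals(object)))
  class(out) <- "summary.sv_fit"
  out
}

#' @export
print.summary.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer %s fit: n = %d, T = %g degC\n",
              x$model, x$n, x$temperature))
  tab <- data.frame(estimate = x$coefficients,
                    std.error = x$param_se[seq_along(x$coefficients)])
  print(tab)
  cat(sprintf("r^2 = %.4f, residual sd = %.4g, converged = %s\n",
              x$r_squared, x$residual_sd, x$converged))
  if (!is.null(x$reason)) cat("reason:", x$reason, "\n")
  invisible(x)
}

#' Plot a Stern-Volmer fit
#'
#' Base-graphics plot of F0/F against molar quencher concentration with
#' the fitted curve and, where available, replicate error bars.
#'
#' @param x An `sv_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sv_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$concentrations, s$ratio_mean,
                 xlab = "[Q] (M)", ylab = expression(F[0] / F),
                 pch = 19, ...)
  if (!is.null(s$ratio_sd)) {
    up <- s$ratio_mean + s$ratio_sd
    lo <- s$ratio_mean - s$ratio_sd
    graphics::arrows(s$concentrations, lo, s$concentrations, up,
                     angle = 90, code = 3, length = 0.03, col = "red")
  }
  qq <- seq(0, max(s$concentrations), length.out = 200)
  graphics::lines(qq, predict(x, qq), lty = 2)
  invisible(x)
}

#' Simulate titration series from a fitted Stern-Volmer model
#'
#' Draws `nsim` synthetic replicate-mean series from the fitted model with
#' multiplicative lognormal noise, the same noise model used by
#' [simulate_series()].
#'
#' @param object An `sv_fit`.
#' @param nsim Number of simulated series.
#' @param seed Integer seed (required for reproducibility).
#' @param noise_cv Fractional coefficient of variation of the multiplicative
#'   noise on each replicate ratio.
#' @param n_replicates Replicates averaged per simulated point.
#' @param ... Unused.
#' @return A list of `quenching_series`.
#' @export
simulate.sv_fit <- function(object, nsim = 1, seed = NULL,
                            noise_cv = 0.01, n_replicates = 3, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  q <- object$series$concentrations
  mu <- predict(object, q)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      noisy_ratio_series(q, mu, noise_cv, n_replicates,
                         temperature = object$series$temperature,
                         crowder = object$series$crowder))
  })
}
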