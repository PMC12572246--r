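#' @export
print.mpod_fit <- function(x, digits = 4, ...) {
  cat("MPOD profile fit (", x$model$kind, "), window ",
      x$window[1], "-", x$window[2], " deg, n = ", length(x$ecc),
      "\n", sep = "")
  cat("  SSE:", signif(x$sse, digits),
      sprintf("a.u.^2 (x1e3: %s)", signif(x$sse * 1e3, digits)),
      "\n  converged:", x$converged,
      " iterations:", x$n_iter,
      " winning start:", x$start_index, "\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.mpod_fit <- function(object, ...) object$model$par

#' @export
deviance.mpod_fit <- function(object, ...) object$sse

#' @export
nobs.mpod_fit <- function(object, ...) length(object$ecc)

#' @export
fitted.mpod_fit <- function(object, ...) predict(object$model, object$ecc)

#' @export
residuals.mpod_fit <- function(object, ...) object$mpod - fitted(object)

#' Predict from a fitted MPOD profile model
#'
#' @param object an `mpod_fit`.
#' @param x eccentricities (degrees); defaults to the fitted abscissae.
#' @param deriv derivative order 0-3, as in [predict.mpod_model()].
#' @param ... unused.
#' @return Numeric vector of model (or derivative) values.
#' @export
predict.mpod_fit <- function(object, x = object$ecc, deriv = 0L, ...) {
  predict(object$model, x, deriv = deriv)
}

#' Summarise a fitted MPOD profile model
#'
#' Augments the fit with the derived shape parameters of [derive_all()]
#' computed over the fitted window.
#'
#' @param object an `mpod_fit`.
#' @param ... passed to [derive_all()].
#' @return An object of class `summary.mpod_fit`.
#' @export
summary.mpod_fit <- function(object, ...) {
  structure(list(fit = object,
                 derived = derive_all(object$model,
                                      domain = object$window, ...),
                 rse = sqrt(object$sse / max(length(object$ecc) -
                                               length(coef(object)), 1))),
            class = "summary.mpod_fit")
}

#' @export
print.summary.mpod_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  residual sd:", signif(x$rse, digits), "a.u.\n\n")
  print(x$derived, digits = digits)
  invisible(x)
}

#' Simulate profiles from a fitted MPOD model
#'
#' Draws new profiles on the fitted abscissae: model curve plus i.i.d.
#' Gaussian noise with standard deviation equal to the fit's residual
#' standard error (or `noise_sd` if given).
#'
#' @param object an `mpod_fit`.
#' @param nsim number of profiles.
#' @param seed optional integer seed.
#' @param noise_sd optional noise standard deviation (a.u.).
#' @param ... unused.
#' @return A list of [mpod_profile()] objects.
#' @export
simulate.mpod_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sd = NULL, ...) {
  if (is.null(noise_sd))
    noise_sd <- sqrt(object$sse / max(length(object$ecc) -
                                        length(coef(object)), 1))
  .with_seed(seed, lapply(seq_len(nsim), function(i)
    render_profile(object$model, grid = object$ecc, noise_sd = noise_sd)))
}

#' Plot a fitted MPOD profile model
#'
#' Data points with the fitted curve; optionally the individual model
#' components and the first/second derivatives.
#'
#' @param x an `mpod_fit`.
#' @param components draw the separate model components?
#' @param derivatives add a second panel with first and second derivatives?
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mpod_fit <- function(x, components = TRUE, derivatives = FALSE, ...) {
  if (derivatives) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
  }
  xs <- seq(min(x$ecc), max(x$ecc), length.out = 400)
  graphics::plot(x$ecc, x$mpod, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "eccentricity (deg)", ylab = "MPOD (a.u.)", ...)
  graphics::lines(xs, predict(x$model, xs), lwd = 2)
  if (components) {
    p <- x$model$par
    comps <- if (x$model$kind == "m3g") list(
      .gauss_term(xs, p[["N1"]], p[["q1"]], p[["g1"]]),
      .gauss_term(xs, p[["N2"]], p[["q2"]], p[["g2"]]),
      .gauss_term(xs, p[["N3"]], p[["q3"]], p[["g3"]]))
    else list(.exp_term(xs, p[["A1"]], p[["p1"]]),
              .gauss_term(xs, p[["A2"]], p[["p2"]], p[["x2"]]))
    for (i in seq_along(comps))
      graphics::lines(xs, comps[[i]], lty = 2, col = i + 1)
  }
  if (derivatives) {
    d1 <- predict(x$model, xs, deriv = 1)
    d2 <- predict(x$model, xs, deriv = 2)
    graphics::plot(xs, d1, type = "l", col = "darkorange", lwd = 2,
                   ylim = range(c(d1, d2)),
                   xlab = "eccentricity (deg)", ylab = "derivative")
    graphics::lines(xs, d2, col = "magenta", lwd = 2)
    graphics::abline(h = 0, lty = 3)
    graphics::legend("bottomright", c("M'", "M''"), lwd = 2, bty = "n",
                     col = c("darkorange", "magenta"))
  }
  invisible(x)
}
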