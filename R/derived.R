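#' Critical points of the second derivative of an MPOD model
#'
#' Locates the zeros, local maxima and local minima of the model's second
#' derivative over the analysis domain and labels up to six of them in
#' ascending-x order along the canonical curvature chain of a declining
#' MPOD profile: `dd1` the first zero, `dd2` the first maximum, `dd3` the
#' second zero, `dd4` the second minimum, `dd5` the third zero and `dd6`
#' the second maximum. The curvature minimum adjacent to 0 degrees counts
#' as the (unreported) first minimum even when it sits on the domain
#' boundary, so that `dd4` is the eccentric curvature minimum that marks an
#' eccentric peak or shoulder. Features are matched to chain positions in
#' scan order (each feature takes the earliest unfilled slot of its type),
#' so the reported labels are always ascending in x; chain positions
#' without a matching feature are absent (`NA`), never errors.
#'
#' The second derivative is scanned on a dense grid; each sign change of the
#' second (zeros) or third (extrema) analytic derivative is then refined by
#' bisection root polishing. Features closer together than `2 * step`
#' (degenerate near-double roots) are merged, keeping the extremum.
#'
#' @param model an [m3g()]/[meg()] model or an `mpod_fit`.
#' @param domain `(lo, hi)` analysis interval in degrees (open at `lo`).
#' @param step scan step in degrees.
#' @return An object of class `mpod_critical_points`: a list with fields
#'   `dd1`..`dd6` (degrees or `NA`) plus the full tables of refined `zeros`,
#'   `maxima` and `minima`.
#' @examples
#' m <- m3g(N = c(1, 0, 0), q = c(1, 1, 1), g = c(0, 0, 0))
#' critical_points(m)  # dd1 = 1/sqrt(2), dd2 = sqrt(3/2)
#' @export
critical_points <- function(model, domain = c(0, 5), step = 1e-3) {
  if (inherits(model, "mpod_fit")) model <- model$model
  .check_model(model)
  stopifnot(length(domain) == 2L, domain[1] < domain[2], step > 0)
  d2 <- function(x) .eval_model(model, x, 2L)
  d3 <- function(x) .eval_model(model, x, 3L)
  xs <- seq(domain[1] + step, domain[2], by = step)
  v2 <- d2(xs); v3 <- d3(xs)

  refine <- function(f, i) {
    stats::uniroot(f, lower = xs[i], upper = xs[i + 1], tol = 1e-12)$root
  }
  ch2 <- which(v2[-1] * v2[-length(v2)] < 0)
  zeros <- vapply(ch2, function(i) refine(d2, i), numeric(1))
  ch3 <- which(v3[-1] * v3[-length(v3)] < 0)
  ext <- vapply(ch3, function(i) refine(d3, i), numeric(1))
  ext_kind <- ifelse(v3[ch3] > 0, "max", "min")

  # merge near-coincident features (within 2*step), extremum wins
  if (length(zeros) && length(ext)) {
    keep <- vapply(zeros, function(z) all(abs(z - ext) > 2 * step),
                   logical(1))
    zeros <- zeros[keep]
  }

  maxima <- sort(ext[ext_kind == "max"])
  minima <- sort(ext[ext_kind == "min"])
  # boundary curvature minimum: second derivative increasing away from 0
  boundary_min <- length(v3) > 0 && v3[1] > 0

  # order-preserving assignment along the canonical feature chain
  # (zero, max, zero, min, zero, max); the curvature minimum nearest 0 is
  # the unreported first minimum, so the chain's "min" slot is dd4
  ev <- data.frame(x = c(zeros, maxima, minima),
                   type = c(rep("zero", length(zeros)),
                            rep("max", length(maxima)),
                            rep("min", length(minima))))
  ev <- ev[order(ev$x), , drop = FALSE]
  slot_type <- c("zero", "max", "zero", "min", "zero", "max")
  dd <- rep(NA_real_, 6L)
  first_min_credit <- !boundary_min
  k <- 1L
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "min" && first_min_credit) {
      first_min_credit <- FALSE
      next
    }
    j <- which(slot_type == ev$type[i] & seq_along(slot_type) >= k &
                 is.na(dd))
    if (!length(j)) next
    dd[j[1]] <- ev$x[i]
    k <- j[1] + 1L
  }

  structure(list(
    dd1 = dd[1], dd2 = dd[2], dd3 = dd[3], dd4 = dd[4], dd5 = dd[5],
    dd6 = dd[6],
    zeros = zeros, maxima = maxima, minima = minima,
    boundary_min = boundary_min, domain = domain),
    class = "mpod_critical_points")
}

#' @export
print.mpod_critical_points <- function(x, digits = 4, ...) {
  v <- unlist(x[c("dd1", "dd2", "dd3", "dd4", "dd5", "dd6")])
  cat("second-derivative critical points (deg), domain",
      x$domain[1], "-", x$domain[2], "\n")
  print(round(v, digits))
  invisible(x)
}

## single-term area: erf closed form when the quadratic coefficient is
## positive, adaptive quadrature otherwise
.term_auc <- function(N, q, g, a, b) {
  if (N == 0) return(0)
  if (q > 0) {
    s <- sqrt(q)
    N * sqrt(pi / q) / 2 * (.erf(s * (b - g)) - .erf(s * (a - g)))
  } else if (q == 0) {
    N * (b - a)
  } else {
    stats::integrate(function(x) N * exp(-q * (x - g)^2), a, b,
                     abs.tol = 1e-9, rel.tol = 1e-10)$value
  }
}

#' Area under an MPOD model curve
#'
#' Integral of the model between two eccentricities (a.u. x deg). Gaussian
#' terms with positive spread use the error-function closed form; terms with
#' non-positive spread (the tail component may have `q3 < 0`) use adaptive
#' quadrature to an absolute tolerance of 1e-9. The exponential term of the
#' two-component model uses its exact antiderivative.
#'
#' @param model an [m3g()]/[meg()] model or an `mpod_fit`.
#' @param a,b integration limits in degrees, `a < b`.
#' @return The area (a.u. x deg).
#' @export
model_auc <- function(model, a, b) {
  if (inherits(model, "mpod_fit")) model <- model$model
  .check_model(model)
  if (!(a < b)) stop("'a' must be smaller than 'b'", call. = FALSE)
  p <- model$par
  if (model$kind == "m3g") {
    .term_auc(p[["N1"]], p[["q1"]], p[["g1"]], a, b) +
      .term_auc(p[["N2"]], p[["q2"]], p[["g2"]], a, b) +
      .term_auc(p[["N3"]], p[["q3"]], p[["g3"]], a, b)
  } else {
    p[["A1"]] / p[["p1"]] * (exp(-p[["p1"]] * a) - exp(-p[["p1"]] * b)) +
      .term_auc(p[["A2"]], p[["p2"]], p[["x2"]], a, b)
  }
}

## volume under the radially symmetric 2D surface: 2 pi int_0^R m(r) r dr
.term_volume <- function(N, q, g, R) {
  if (N == 0) return(0)
  if (q > 0) {
    s <- sqrt(q)
    # int r e^{-q(r-g)^2} dr = -e^{-q u^2}/(2q) + g sqrt(pi/q)/2 erf(s u)
    F <- function(r) {
      u <- r - g
      -exp(-q * u^2) / (2 * q) + g * sqrt(pi / q) / 2 * .erf(s * u)
    }
    2 * pi * N * (F(R) - F(0))
  } else {
    2 * pi * stats::integrate(function(r) N * exp(-q * (r - g)^2) * r,
                              0, R, abs.tol = 1e-9,
                              rel.tol = 1e-10)$value
  }
}

#' Macular pigment volume within a radius
#'
#' Relative pigment volume under the radially symmetric 2D surface implied
#' by the profile model: \eqn{2\pi \int_0^R m(r)\, r\, dr}. Units are
#' relative (a.u. x deg^2); instrument volume calibrations are
#' machine-specific and not reproduced.
#'
#' @param model an [m3g()]/[meg()] model or an `mpod_fit`.
#' @param radius outer radius in degrees, > 0.
#' @return Relative volume (a.u. x deg^2).
#' @export
model_volume <- function(model, radius) {
  if (inherits(model, "mpod_fit")) model <- model$model
  .check_model(model)
  if (radius <= 0) stop("'radius' must be positive", call. = FALSE)
  p <- model$par
  if (model$kind == "m3g") {
    .term_volume(p[["N1"]], p[["q1"]], p[["g1"]], radius) +
      .term_volume(p[["N2"]], p[["q2"]], p[["g2"]], radius) +
      .term_volume(p[["N3"]], p[["q3"]], p[["g3"]], radius)
  } else {
    A <- p[["A1"]]; pw <- p[["p1"]]
    expo <- 2 * pi * A * (1 / pw^2 - exp(-pw * radius) *
                            (radius / pw + 1 / pw^2))
    expo + .term_volume(p[["A2"]], p[["p2"]], p[["x2"]], radius)
  }
}

#' Half-height radius of an MPOD profile model
#'
#' The eccentricity at which the modelled profile falls to half its central
#' amplitude `M(0)/2`. In a non-monotonic profile the half-height level can
#' be crossed several times, so the default convention returns the last
#' down-crossing after which the model stays below half height through the
#' end of the domain; `convention = "first"` returns the first
#' down-crossing instead. `NA` when the model never settles below half
#' height within the domain.
#'
#' @param model an [m3g()]/[meg()] model or an `mpod_fit`.
#' @param domain `(0, hi)` search interval in degrees.
#' @param convention `"last_sustained"` (default) or `"first"`.
#' @param step scan step in degrees.
#' @return The half-height radius in degrees, or `NA`.
#' @export
half_height_radius <- function(model, domain = c(0, 5),
                               convention = c("last_sustained", "first"),
                               step = 1e-3) {
  if (inherits(model, "mpod_fit")) model <- model$model
  .check_model(model)
  convention <- match.arg(convention)
  half <- .eval_model(model, 0)[1] / 2
  f <- function(x) .eval_model(model, x) - half
  xs <- seq(domain[1] + step, domain[2], by = step)
  v <- f(xs)
  dn <- which(v[-length(v)] > 0 & v[-1] <= 0)
  if (!length(dn)) return(NA_real_)
  roots <- vapply(dn, function(i)
    stats::uniroot(f, lower = xs[i], upper = xs[i + 1],
                   tol = 1e-12)$root, numeric(1))
  if (convention == "first") return(roots[1])
  for (r in rev(roots)) {
    after <- v[xs > r + step]
    if (!length(after) || all(after < 0)) return(r)
  }
  NA_real_
}

#' Shape classification of an MPOD profile model
#'
#' Classifies the modelled profile as `"eccentric_peak"` (the first
#' derivative has a positive interval beyond the central zone, i.e. a true
#' secondary maximum), `"shoulder"` (monotone decline but with an eccentric
#' curvature minimum `dd4` - a gradient relaxation without sign change), or
#' `"central_peak_monotonic"` otherwise.
#'
#' Monotonicity is judged on `[centre_tol, hi]`: the fitted central
#' component's centre is allowed to sit anywhere within `|g1| <= 0.1` deg,
#' so a central peak displaced by less than `centre_tol` from zero is still
#' a central peak, not an eccentric one.
#'
#' @param model an [m3g()]/[meg()] model or an `mpod_fit`.
#' @param domain `(0, hi)` analysis interval in degrees.
#' @param centre_tol central exclusion radius (degrees) for the
#'   monotonicity test.
#' @param step scan step in degrees.
#' @return A character scalar.
#' @export
classify_profile <- function(model, domain = c(0, 5), centre_tol = 0.1,
                             step = 1e-3) {
  if (inherits(model, "mpod_fit")) model <- model$model
  .check_model(model)
  if (.is_monotone_decline(model, domain, centre_tol, step)) {
    cp <- critical_points(model, domain = domain, step = step)
    if (!is.na(cp$dd4)) "shoulder" else "central_peak_monotonic"
  } else "eccentric_peak"
}

.is_monotone_decline <- function(model, domain, centre_tol, step) {
  xs <- seq(max(domain[1], centre_tol), domain[2], by = step)
  all(.eval_model(model, xs, 1L) <= 0)
}

#' All derived parameters of an MPOD profile model
#'
#' Assembles the derived shape parameters: the central amplitude
#' `A0 = M(0)`; the eccentric-peak/shoulder amplitude `A_ecc = M(dd4)` when
#' the eccentric curvature minimum `dd4` exists; the areas under the curve
#' from 0 to 0.2 degrees (`AUC02`) and 0 to 5 degrees (`AUC5`); the
#' half-height radius `HHr`; the monotonicity flag (first derivative
#' non-positive beyond the central zone); the profile shape class; and the
#' critical points `dd1`..`dd6`.
#'
#' @inheritParams classify_profile
#' @param hhr_convention passed to [half_height_radius()].
#' @return An object of class `mpod_derived` (a list with the above
#'   fields; absent features are `NA`).
#' @export
derive_all <- function(model, domain = c(0, 5), centre_tol = 0.1,
                       step = 1e-3,
                       hhr_convention = "last_sustained") {
  if (inherits(model, "mpod_fit")) model <- model$model
  .check_model(model)
  cp <- critical_points(model, domain = domain, step = step)
  A0 <- .eval_model(model, 0)[1]
  monotone <- .is_monotone_decline(model, domain, centre_tol, step)
  structure(list(
    A0 = A0,
    A_ecc = if (!is.na(cp$dd4)) .eval_model(model, cp$dd4)[1] else NA_real_,
    AUC02 = model_auc(model, 0, 0.2),
    AUC5 = model_auc(model, 0, min(5, domain[2])),
    HHr = half_height_radius(model, domain = domain,
                             convention = hhr_convention, step = step),
    monotonic = monotone,
    profile_class = if (!monotone) "eccentric_peak"
                    else if (!is.na(cp$dd4)) "shoulder"
                    else "central_peak_monotonic",
    critical_points = cp,
    domain = domain), class = "mpod_derived")
}

#' @export
print.mpod_derived <- function(x, digits = 4, ...) {
  cat("derived MPOD profile parameters (domain",
      x$domain[1], "-", x$domain[2], "deg)\n")
  v <- c(A0 = x$A0, A_ecc = x$A_ecc, AUC02 = x$AUC02, AUC5 = x$AUC5,
         HHr = x$HHr)
  print(round(v, digits))
  cat("  monotone decline:", x$monotonic,
      "  class:", x$profile_class, "\n")
  print(x$critical_points, digits = digits)
  invisible(x)
}
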