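#' Three-Gaussian MPOD profile model
#'
#' Constructs the three-Gaussian-component model of the macular pigment
#' optical density (MPOD) radial profile,
#' \deqn{M(x) = \sum_{i=1}^{3} N_i \exp\{-q_i (x - g_i)^2\},}
#' where `x` is retinal eccentricity in degrees of visual angle. By the
#' fitting convention used throughout the package, component 1 carries the
#' central peak, component 2 any intermediate shoulder or eccentric peak,
#' and component 3 the peripheral tail-off. The tail spread `q3` may be
#' negative (a fitted-tail artefact in which the third component grows
#' slowly away from its distant centre `g3`); evaluation, differentiation
#' and integration all handle that case.
#'
#' @param N numeric length 3; component amplitudes (MPOD a.u.), all >= 0.
#' @param q numeric length 3; component spreads (deg^-2). `q[1]` and `q[2]`
#'   must be positive; `q[3]` may take either sign.
#' @param g numeric length 3; component centre eccentricities (degrees).
#'
#' @return An object of class `mpod_model` with `kind = "m3g"`.
#' @seealso [meg()], [predict.mpod_model()], [fit_mpod()]
#' @examples
#' m <- m3g(N = c(0.200, 0.250, 0.039),
#'          q = c(14.515, 1.700, -0.020),
#'          g = c(-0.017, 0.562, 10.000))
#' predict(m, x = c(0, 0.5, 1, 2))
#' @export
m3g <- function(N, q, g) {
  stopifnot(length(N) == 3, length(q) == 3, length(g) == 3)
  N <- unname(as.numeric(N)); q <- unname(as.numeric(q))
  g <- unname(as.numeric(g))
  par <- c(N1 = N[1], N2 = N[2], N3 = N[3],
           q1 = q[1], q2 = q[2], q3 = q[3],
           g1 = g[1], g2 = g[2], g3 = g[3])
  if (!all(is.finite(par)))
    stop("m3g parameters must be finite", call. = FALSE)
  if (any(N < 0))
    stop("m3g amplitudes N must be non-negative", call. = FALSE)
  if (q[1] <= 0 || q[2] <= 0)
    stop("m3g spreads q1 and q2 must be positive", call. = FALSE)
  structure(list(kind = "m3g", par = par), class = "mpod_model")
}

#' Exponential-plus-Gaussian MPOD profile model
#'
#' Constructs the legacy two-component model of the MPOD radial profile,
#' \deqn{M(x) = A_1 e^{-p_1 x} + A_2 e^{-p_2 (x - x_2)^2},}
#' the sum of a declining exponential (central peak and tail) and a single
#' Gaussian (eccentric shoulder/peak), expressed in base e. Use
#' [meg_to_base10()] to convert amplitudes to the base-10 form used in
#' older literature.
#'
#' @param A1 exponential amplitude (a.u.), >= 0.
#' @param p1 exponential decay constant (deg^-1), > 0.
#' @param A2 Gaussian amplitude (a.u.), >= 0.
#' @param p2 Gaussian spread (deg^-2), > 0.
#' @param x2 Gaussian peak eccentricity (degrees), >= 0.
#'
#' @return An object of class `mpod_model` with `kind = "meg"`.
#' @examples
#' m <- meg(A1 = 0.5, p1 = 2, A2 = 0.2, p2 = 3, x2 = 0.7)
#' predict(m, x = seq(0, 5, by = 0.5))
#' @export
meg <- function(A1, p1, A2, p2, x2) {
  par <- c(A1 = unname(A1), p1 = unname(p1), A2 = unname(A2),
           p2 = unname(p2), x2 = unname(x2))
  if (!all(is.finite(par)))
    stop("meg parameters must be finite", call. = FALSE)
  if (A1 < 0 || A2 < 0)
    stop("meg amplitudes A1, A2 must be non-negative", call. = FALSE)
  if (p1 <= 0 || p2 <= 0)
    stop("meg decay/spread p1, p2 must be positive", call. = FALSE)
  if (x2 < 0)
    stop("meg Gaussian centre x2 must be non-negative", call. = FALSE)
  structure(list(kind = "meg", par = par), class = "mpod_model")
}

## closed-form evaluation of one Gaussian term N exp(-q (x-g)^2) and its
## derivatives up to order 3 (orders follow from direct differentiation)
.gauss_term <- function(x, N, q, g, deriv = 0L) {
  u <- x - g
  e <- exp(-q * u^2)
  switch(deriv + 1L,
    N * e,
    -2 * q * N * u * e,
    N * e * (4 * q^2 * u^2 - 2 * q),
    N * e * (12 * q^2 * u - 8 * q^3 * u^3))
}

.exp_term <- function(x, A, p, deriv = 0L) {
  (-p)^deriv * A * exp(-p * x)
}

.eval_model <- function(object, x, deriv = 0L) {
  p <- object$par
  if (object$kind == "m3g") {
    .gauss_term(x, p[["N1"]], p[["q1"]], p[["g1"]], deriv) +
      .gauss_term(x, p[["N2"]], p[["q2"]], p[["g2"]], deriv) +
      .gauss_term(x, p[["N3"]], p[["q3"]], p[["g3"]], deriv)
  } else {
    .exp_term(x, p[["A1"]], p[["p1"]], deriv) +
      .gauss_term(x, p[["A2"]], p[["p2"]], p[["x2"]], deriv)
  }
}

.check_model <- function(object) {
  if (!inherits(object, "mpod_model") || is.null(object$kind) ||
      !object$kind %in% c("m3g", "meg"))
    stop("not a valid 'mpod_model' object", call. = FALSE)
  np <- if (object$kind == "m3g") 9L else 5L
  nm <- if (object$kind == "m3g")
    c("N1", "N2", "N3", "q1", "q2", "q3", "g1", "g2", "g3")
  else c("A1", "p1", "A2", "p2", "x2")
  if (length(object$par) != np || !identical(names(object$par), nm))
    stop("model parameters do not match model kind '", object$kind, "'",
         call. = FALSE)
  invisible(object)
}

#' Evaluate an MPOD model or its analytic derivatives
#'
#' Evaluates the model curve, or one of its closed-form derivatives, at the
#' given eccentricities. Derivatives are analytic (no finite differencing):
#' for a Gaussian term \eqn{N e^{-q(x-g)^2}} the first derivative is
#' \eqn{-2qN(x-g)e^{-q(x-g)^2}}, the second
#' \eqn{Ne^{-q(x-g)^2}(4q^2(x-g)^2 - 2q)}, and so on; for the exponential
#' term \eqn{A e^{-px}} the k-th derivative is \eqn{(-p)^k A e^{-px}}.
#'
#' @param object an [m3g()] or [meg()] model.
#' @param x numeric vector of eccentricities (degrees); a scalar is treated
#'   as a length-1 vector.
#' @param deriv derivative order, one of 0 (the curve itself), 1, 2 or 3.
#' @param ... unused.
#'
#' @return Numeric vector the same length as `x`.
#' @examples
#' m <- m3g(N = c(1, 0, 0), q = c(1, 1, 1), g = c(0, 0, 0))
#' predict(m, 0, deriv = 2)  # -2q at the centre of a unit Gaussian
#' @export
predict.mpod_model <- function(object, x, deriv = 0L, ...) {
  .check_model(object)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  deriv <- as.integer(deriv)
  if (length(deriv) != 1L || !deriv %in% 0:3)
    stop("'deriv' must be one of 0, 1, 2, 3", call. = FALSE)
  .eval_model(object, as.numeric(x), deriv)
}

#' Convert an exponential+Gaussian model between amplitude bases
#'
#' The exponential+Gaussian model is handled in base e; the original
#' formulation in the literature is base 10. Conversion divides (base e to
#' base 10) or multiplies (base 10 to base e) the two amplitudes `A1`, `A2`
#' by \eqn{\ln 10}; the decay, spread and centre parameters are unchanged.
#' The two functions are exact inverses.
#'
#' @param object an [meg()] model.
#' @return An [meg()] model with converted amplitudes.
#' @export
meg_to_base10 <- function(object) {
  .check_model(object)
  if (object$kind != "meg") stop("base conversion applies to 'meg' models",
                                 call. = FALSE)
  p <- object$par
  meg(p[["A1"]] / log(10), p[["p1"]], p[["A2"]] / log(10), p[["p2"]],
      p[["x2"]])
}

#' @rdname meg_to_base10
#' @export
meg_to_base_e <- function(object) {
  .check_model(object)
  if (object$kind != "meg") stop("base conversion applies to 'meg' models",
                                 call. = FALSE)
  p <- object$par
  meg(p[["A1"]] * log(10), p[["p1"]], p[["A2"]] * log(10), p[["p2"]],
      p[["x2"]])
}

#' @export
print.mpod_model <- function(x, digits = 4, ...) {
  lbl <- c(m3g = "three-Gaussian MPOD profile model",
           meg = "exponential+Gaussian MPOD profile model")[x$kind]
  cat(lbl, "\n")
  print(round(x$par, digits))
  invisible(x)
}

#' @export
coef.mpod_model <- function(object, ...) object$par

#' Serialize and restore MPOD models as flat key-value lists
#'
#' `as.list()` flattens a model into `list(kind = ..., N1 = ..., ...)`
#' suitable for JSON/YAML storage; `mpod_model_from_list()` restores it.
#'
#' @param x an `mpod_model` (for `as.list`) or a named list with a `kind`
#'   element plus the model's parameter fields.
#' @param ... unused.
#' @return A plain list, or an `mpod_model`.
#' @export
as.list.mpod_model <- function(x, ...) {
  c(list(kind = x$kind), as.list(x$par))
}

#' @rdname as.list.mpod_model
#' @export
mpod_model_from_list <- function(x) {
  if (is.null(x$kind)) stop("list lacks a 'kind' element", call. = FALSE)
  num <- function(k) {
    v <- x[[k]]
    if (is.null(v)) stop("missing model parameter '", k, "'", call. = FALSE)
    as.numeric(v)
  }
  if (x$kind == "m3g") {
    m3g(N = c(num("N1"), num("N2"), num("N3")),
        q = c(num("q1"), num("q2"), num("q3")),
        g = c(num("g1"), num("g2"), num("g3")))
  } else if (x$kind == "meg") {
    meg(num("A1"), num("p1"), num("A2"), num("p2"), num("x2"))
  } else stop("unknown model kind '", x$kind, "'", call. = FALSE)
}
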