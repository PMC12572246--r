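## reference distributions for the synthetic generator: per-parameter
## means/sds of the three-Gaussian model over a healthy adult cohort, and
## foveal morphometry distributions (degrees of visual angle; thicknesses
## in micrometers)
.m3g_param_means <- c(N1 = 0.224, N2 = 0.296, N3 = 0.097,
                      q1 = 32.092, q2 = 1.938, q3 = -0.009,
                      g1 = -0.027, g2 = 0.547, g3 = 5.345)
.m3g_param_sds <- c(N1 = 0.102, N2 = 0.125, N3 = 0.092,
                    q1 = 43.978, q2 = 0.792, q3 = 0.032,
                    g1 = 0.067, g2 = 0.265, g3 = 5.243)
.morph_means <- c(FAZf = 2.27, FAZm = 2.03, FAZer = 0.91, AvCRT = 274,
                  fov_th = 231, bwlht = 123, Fr = 0.81, Pr = 3.96,
                  fov_ang = 168)
.morph_sds <- c(FAZf = 0.41, FAZm = 0.39, FAZer = 0.19, AvCRT = 14,
                fov_th = 14, bwlht = 22, Fr = 0.16, Pr = 0.44,
                fov_ang = 3)

#' Specification of a synthetic MPOD cohort
#'
#' Describes a synthetic cohort standing in for a measured data set:
#' three-Gaussian profile parameters drawn from independent truncated
#' normals, additive profile measurement noise, foveal morphometry drawn
#' from normal distributions, and a linear linkage between each eye's
#' realised radial-extent landmark `dd6` and the morphometry triplet
#' (FAZer, bwlht, Pr) with standardized coefficients `dd6_link` and
#' population coefficient of determination `target_r2`.
#'
#' Defaults reproduce the reference cohort conditions: 48 eyes, parameter
#' means/sds from the fitted-population table, noise sd 0.01 a.u.,
#' FAZer 0.91 +/- 0.19 deg, bwlht 123 +/- 22 um, Pr 3.96 +/- 0.44 deg, and
#' dd6 = 0.605 FAZer + 0.426 bwlht + 0.190 Pr (standardized) with R^2 0.81.
#'
#' @param n_eyes number of eyes (>= 1).
#' @param param_means,param_sds named numeric vectors over
#'   `N1,N2,N3,q1,q2,q3,g1,g2,g3`.
#' @param bounds truncation box, as [default_bounds()] for `"m3g"`.
#' @param noise_sd additive profile noise sd (a.u.), >= 0.
#' @param morph_means,morph_sds named numeric vectors over the morphometry
#'   fields `FAZf,FAZm,FAZer,AvCRT,fov_th,bwlht,Fr,Pr,fov_ang`.
#' @param dd6_link standardized regression coefficients of dd6 on
#'   `c(FAZer, bwlht, Pr)`.
#' @param target_r2 population R^2 of the dd6 linkage, in (0, 1].
#' @param seed integer seed.
#' @return An object of class `mpod_cohort_spec`.
#' @seealso [sample_cohort()]
#' @export
cohort_spec <- function(n_eyes = 48L,
                        param_means = .m3g_param_means,
                        param_sds = .m3g_param_sds,
                        bounds = default_bounds("m3g"),
                        noise_sd = 0.01,
                        morph_means = .morph_means,
                        morph_sds = .morph_sds,
                        dd6_link = c(FAZer = 0.605, bwlht = 0.426,
                                     Pr = 0.190),
                        target_r2 = 0.81,
                        seed = 1L) {
  pn <- names(.m3g_param_means)
  if (n_eyes < 1L) stop("'n_eyes' must be >= 1", call. = FALSE)
  if (!all(pn %in% names(param_means)) || !all(pn %in% names(param_sds)))
    stop("param_means/param_sds must cover ", paste(pn, collapse = ","),
         call. = FALSE)
  if (any(param_sds[pn] < 0) || any(morph_sds < 0))
    stop("standard deviations must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (target_r2 <= 0 || target_r2 > 1)
    stop("'target_r2' must be in (0, 1]", call. = FALSE)
  # feasibility of the truncation: each parameter must retain real mass
  mass <- stats::pnorm(bounds$upper[pn], param_means[pn], param_sds[pn]) -
    stats::pnorm(bounds$lower[pn], param_means[pn], param_sds[pn])
  if (any(mass < 1e-4))
    stop("infeasible truncation for parameter(s): ",
         paste(pn[mass < 1e-4], collapse = ", "), call. = FALSE)
  structure(list(n_eyes = as.integer(n_eyes),
                 param_means = param_means[pn], param_sds = param_sds[pn],
                 bounds = bounds, noise_sd = noise_sd,
                 morph_means = morph_means, morph_sds = morph_sds,
                 dd6_link = dd6_link, target_r2 = target_r2,
                 seed = as.integer(seed)),
            class = "mpod_cohort_spec")
}

## vectorized truncated-normal rejection sampler, capped proposals per draw
.rtruncnorm <- function(n, mean, sd, lo, hi, cap = 1e4) {
  if (sd == 0) {
    if (mean < lo || mean > hi)
      stop("degenerate truncated normal outside bounds", call. = FALSE)
    return(rep(mean, n))
  }
  out <- rep(NA_real_, n)
  tries <- 0L
  while (anyNA(out)) {
    if (tries >= cap)
      stop("truncated-normal rejection cap exceeded", call. = FALSE)
    miss <- which(is.na(out))
    cand <- stats::rnorm(length(miss), mean, sd)
    ok <- cand >= lo & cand <= hi
    out[miss[ok]] <- cand[ok]
    tries <- tries + 1L
  }
  out
}

## equicorrelated predictor correlation matrix making the standardized
## linkage betas b achieve R^2 = b' S b = r2
.link_structure <- function(b, r2) {
  k <- length(b)
  cross <- sum(outer(b, b)[upper.tri(diag(k))])
  rho <- if (cross > 0) (r2 - sum(b^2)) / (2 * cross) else 0
  if (rho <= -1 / (k - 1) + 1e-9 || rho > 1)
    stop("dd6 linkage infeasible: implied predictor correlation ",
         signif(rho, 3), call. = FALSE)
  S <- matrix(rho, k, k); diag(S) <- 1
  r <- as.numeric(S %*% b)
  C <- S - tcrossprod(r)      # residual covariance of predictors given dd6
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("dd6 linkage infeasible: requested R^2 too large for the betas",
         call. = FALSE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  list(S = S, r = r, L = L)
}

#' Draw a synthetic cohort of eyes
#'
#' Samples per-eye three-Gaussian profile parameters from independent
#' truncated normals, computes each eye's realised `dd6` (the eccentric
#' curvature maximum marking the radial extent of pigment), and generates
#' foveal morphometry linked to `dd6`: on standardized scales the triplet
#' (FAZer, bwlht, Pr) is drawn conditional on `dd6` so that the population
#' regression of `dd6` on the triplet has the specified standardized
#' coefficients and R^2. The FAZ diameter metrics (FAZf, FAZm) share a
#' common factor with FAZer (pairwise correlation about 0.98); the remaining
#' morphometry fields are independent normals. With `target_r2 = 1` the
#' standardized `dd6` equals the linear combination exactly.
#'
#' @param spec an [cohort_spec()].
#' @param include_summaries also compute per-eye MPOD summary measures
#'   (model values at 0.2/1/2/3 deg, the profile peak, and relative pigment
#'   volumes within those radii)?
#' @param dd_step scan step for the per-eye critical-point search.
#' @return A data frame (class `mpod_cohort`) with one row per eye:
#'   `eye_id`, the morphometry fields, generator-truth parameters prefixed
#'   `true_`, the realised `dd6`, and optionally the MPOD summaries.
#' @export
sample_cohort <- function(spec, include_summaries = FALSE,
                          dd_step = 1e-3) {
  stopifnot(inherits(spec, "mpod_cohort_spec"))
  pn <- names(spec$param_means)
  n <- spec$n_eyes
  .with_seed(spec$seed, {
    P <- sapply(pn, function(k)
      .rtruncnorm(n, spec$param_means[[k]], spec$param_sds[[k]],
                  spec$bounds$lower[[k]], spec$bounds$upper[[k]]))
    P <- matrix(P, nrow = n, dimnames = list(NULL, pn))

    dd6 <- vapply(seq_len(n), function(i) {
      m <- m3g(N = P[i, 1:3], q = P[i, 4:6], g = P[i, 7:9])
      critical_points(m, domain = c(0, 5), step = dd_step)$dd6
    }, numeric(1))

    # linked morphometry triplet on standardized scales
    b <- spec$dd6_link
    ls <- .link_structure(b, spec$target_r2)
    k <- length(b)
    X <- matrix(NA_real_, n, k, dimnames = list(NULL, names(b)))
    has <- !is.na(dd6)
    if (sum(has) >= 2L) {
      z <- (dd6[has] - mean(dd6[has])) / stats::sd(dd6[has])
      W <- matrix(stats::rnorm(sum(has) * k), ncol = k)
      X[has, ] <- z %*% t(ls$r) + W %*% t(ls$L)
    }
    if (any(!has)) {
      W <- matrix(stats::rnorm(sum(!has) * k), ncol = k)
      X[!has, ] <- W %*% chol(ls$S)
    }

    mm <- spec$morph_means; ms <- spec$morph_sds
    morph <- data.frame(
      FAZer = mm[["FAZer"]] + ms[["FAZer"]] * X[, "FAZer"],
      bwlht = mm[["bwlht"]] + ms[["bwlht"]] * X[, "bwlht"],
      Pr = mm[["Pr"]] + ms[["Pr"]] * X[, "Pr"])

    # FAZ diameter metrics share a common factor with FAZer
    lam <- 0.99
    zf <- lam * X[, "FAZer"] + sqrt(1 - lam^2) * stats::rnorm(n)
    zm <- lam * X[, "FAZer"] + sqrt(1 - lam^2) * stats::rnorm(n)
    morph$FAZf <- mm[["FAZf"]] + ms[["FAZf"]] * zf
    morph$FAZm <- mm[["FAZm"]] + ms[["FAZm"]] * zm
    viol <- which(morph$FAZer > morph$FAZf)
    for (i in viol) {   # redraw the idiosyncratic part; violations are rare
      reps <- 0L
      while (morph$FAZer[i] > morph$FAZf[i] && reps < 1e4) {
        morph$FAZf[i] <- mm[["FAZf"]] + ms[["FAZf"]] *
          (lam * X[i, "FAZer"] + sqrt(1 - lam^2) * stats::rnorm(1))
        reps <- reps + 1L
      }
    }
    for (v in c("AvCRT", "fov_th", "Fr", "fov_ang"))
      morph[[v]] <- mm[[v]] + ms[[v]] * stats::rnorm(n)

    out <- data.frame(eye_id = sprintf("eye%03d", seq_len(n)),
                      morph[, c("FAZf", "FAZm", "FAZer", "AvCRT",
                                "fov_th", "bwlht", "Fr", "Pr",
                                "fov_ang")])
    colnames(P) <- paste0("true_", pn)
    out <- cbind(out, P)
    out$dd6 <- dd6

    if (include_summaries) {
      grid <- seq(0, 6, by = 0.01)
      for (i in seq_len(n)) {
        m <- m3g(N = P[i, 1:3], q = P[i, 4:6], g = P[i, 7:9])
        out$ODrad02[i] <- predict(m, 0.2)
        out$ODrad1[i] <- predict(m, 1)
        out$ODrad2[i] <- predict(m, 2)
        out$ODrad3[i] <- predict(m, 3)
        out$Peak[i] <- max(predict(m, grid))
        out$sumV02[i] <- model_volume(m, 0.2)
        out$sumV1[i] <- model_volume(m, 1)
        out$sumV2[i] <- model_volume(m, 2)
        out$sumV3[i] <- model_volume(m, 3)
      }
    }
    class(out) <- c("mpod_cohort", "data.frame")
    attr(out, "spec") <- spec
    out
  })
}

#' Model for one eye of a synthetic cohort
#'
#' @param cohort a cohort data frame from [sample_cohort()].
#' @param i row index.
#' @return The eye's generator-truth [m3g()] model.
#' @export
cohort_model <- function(cohort, i) {
  m3g(N = as.numeric(cohort[i, c("true_N1", "true_N2", "true_N3")]),
      q = as.numeric(cohort[i, c("true_q1", "true_q2", "true_q3")]),
      g = as.numeric(cohort[i, c("true_g1", "true_g2", "true_g3")]))
}

#' Render a noisy radial profile from a model
#'
#' Evaluates the model on a grid and adds i.i.d. Gaussian measurement noise,
#' emulating the radial export of a dual-wavelength autofluorescence
#' instrument.
#'
#' @param model an [m3g()]/[meg()] model.
#' @param grid eccentricity grid (degrees); defaults to [default_grid()].
#' @param noise_sd noise standard deviation (a.u.), >= 0.
#' @param seed optional integer seed.
#' @return An [mpod_profile()] whose `sd` column records `noise_sd`.
#' @export
render_profile <- function(model, grid = default_grid(), noise_sd = 0.01,
                           seed = NULL) {
  .check_model(model)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  y <- predict(model, grid)
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  mpod_profile(grid, y, sd = rep(noise_sd, length(grid)))
}

#' Render a radially symmetric 2D MPOD map from a model
#'
#' Each pixel takes the model value at its angular distance from the centre,
#' plus optional i.i.d. Gaussian noise; a test-bench counterpart of
#' [extract_radial_profile()].
#'
#' @param model an [m3g()]/[meg()] model.
#' @param size_px image side length in pixels (square image).
#' @param scale degrees per pixel, > 0.
#' @param center optional (row, col) sub-pixel centre; defaults to the image
#'   midpoint.
#' @param noise_sd pixel noise sd (a.u.).
#' @param seed optional integer seed.
#' @return An [mpod_map()].
#' @export
render_map <- function(model, size_px = 601L, scale = 0.02, center = NULL,
                       noise_sd = 0, seed = NULL) {
  .check_model(model)
  if (scale <= 0) stop("'scale' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (is.null(center)) center <- rep((size_px + 1) / 2, 2)
  if (center[1] < 1 || center[1] > size_px ||
      center[2] < 1 || center[2] > size_px)
    stop("'center' lies outside the image", call. = FALSE)
  rr <- (seq_len(size_px) - center[1]) * scale
  cc <- (seq_len(size_px) - center[2]) * scale
  d <- sqrt(outer(rr^2, cc^2, `+`))
  px <- matrix(predict(model, as.numeric(d)), size_px, size_px)
  if (noise_sd > 0)
    px <- px + .with_seed(seed,
                          matrix(stats::rnorm(size_px^2, 0, noise_sd),
                                 size_px, size_px))
  mpod_map(px, center, scale)
}
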