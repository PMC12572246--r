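test_that("unit-Gaussian critical points match the closed forms", {
  ug <- m3g(N = c(1, 0, 0), q = c(1, 1, 1), g = c(0, 0, 0))
  cp <- critical_points(ug, domain = c(0, 5))
  expect_equal(cp$dd1, 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(cp$dd2, sqrt(3 / 2), tolerance = 1e-6)
  expect_true(all(is.na(unlist(cp[c("dd3", "dd4", "dd5", "dd6")]))))
  expect_equal(half_height_radius(ug), sqrt(log(2)), tolerance = 1e-6)
  expect_equal(model_auc(ug, 0, 8), sqrt(pi) / 2, tolerance = 1e-9)
})

test_that("grand-mean critical points agree with the published values", {
  # recomputed from the 3-dp printed parameters; residual tolerance is the
  # input-rounding sensitivity
  cp <- critical_points(grand_mean_model(), domain = c(0, 5))
  dd <- unlist(cp[paste0("dd", 1:6)])
  expect_equal(dd, printed_grand_mean$dd, tolerance = 0.02)
  # tighter agreement with an independent finite-difference oracle
  oracle <- c(dd1 = 0.17595, dd2 = 0.29633, dd3 = 0.50232,
              dd4 = 0.68682, dd5 = 1.08779, dd6 = 1.49776)
  expect_equal(unname(dd), unname(oracle), tolerance = 5e-4)
})

test_that("reported second-derivative zeros are true roots with the right
           sign pattern", {
  set.seed(23)
  n_checked <- 0
  for (i in 1:40) {
    m <- random_m3g()
    cp <- critical_points(m, domain = c(0, 5))
    for (z in cp$zeros)
      expect_lt(abs(predict(m, z, deriv = 2)), 1e-8)
    dd <- unlist(cp[paste0("dd", 1:6)])
    if (!anyNA(dd)) {
      n_checked <- n_checked + 1
      expect_true(all(diff(dd) > 0), label = sprintf("ordering draw %d", i))
      d2 <- function(x) predict(m, x, deriv = 2)
      expect_lt(d2(dd[["dd1"]] / 2), 0)    # concave inside the first zero
      expect_gt(d2(dd[["dd2"]]), 0)        # convex at the first maximum
      expect_lt(d2(dd[["dd4"]]), 0)        # concave at the eccentric min
    }
  }
  expect_gt(n_checked, 0)
})

test_that("critical-point ordering holds over many random draws", {
  set.seed(31)
  for (i in 1:1000) {
    m <- random_m3g()
    dd <- unlist(critical_points(m, domain = c(0, 5))[paste0("dd", 1:6)])
    dd <- dd[!is.na(dd)]
    if (length(dd) > 1)
      expect_true(all(diff(dd) > 0), label = sprintf("draw %d", i))
  }
})

test_that("areas under the curve are additive and match quadrature", {
  gm <- grand_mean_model()
  expect_equal(model_auc(gm, 0, 0.2) + model_auc(gm, 0.2, 5),
               model_auc(gm, 0, 5), tolerance = 1e-9)
  # closed form (erf) against adaptive quadrature for positive spreads
  set.seed(17)
  for (i in 1:10) {
    m <- random_m3g()
    p <- coef(m)
    mq <- m3g(N = p[1:3], q = pmax(p[4:6], c(2, 0.1, 0.001)), g = p[7:9])
    quad <- stats::integrate(function(x) predict(mq, x), 0, 5,
                             rel.tol = 1e-12)$value
    expect_equal(model_auc(mq, 0, 5), quad, tolerance = 1e-9)
  }
  expect_error(model_auc(gm, 2, 2), "smaller")
})

test_that("grand-mean areas and amplitudes match within rounding limits", {
  gm <- grand_mean_model()
  d <- derive_all(gm)
  # quadrature oracle values from the printed parameters
  expect_equal(d$AUC02, 0.1219878, tolerance = 1e-6)
  expect_equal(d$AUC5, 1.02111, tolerance = 1e-5)
  expect_equal(d$A_ecc, 0.4646, tolerance = 1e-3)
  # published values reflect unrounded fit parameters; ~3% rounding gap
  expect_equal(d$A0, printed_grand_mean$A0, tolerance = 0.03)
  expect_equal(d$AUC5, printed_grand_mean$AUC5, tolerance = 0.03)
})

test_that("half-height radius follows the sustained-crossing convention", {
  gm <- grand_mean_model()
  expect_equal(half_height_radius(gm), 1.176166, tolerance = 1e-4)
  # a model that never settles below half height has no HHr
  flat <- m3g(N = c(0.5, 0, 0), q = c(1e-9, 1, 1), g = c(0, 0, 0))
  expect_true(is.na(half_height_radius(flat)))
  # non-monotonic profile: eccentric bump pushes the curve back above half
  bump <- m3g(N = c(0.4, 0.35, 0), q = c(30, 8, 1), g = c(0, 1.2, 0))
  first <- half_height_radius(bump, convention = "first")
  last <- half_height_radius(bump)
  expect_lt(first, last)
})

test_that("profiles classify into the three qualitative shapes", {
  pure <- m3g(N = c(0.5, 0, 0), q = c(5, 1, 1), g = c(0, 0, 0))
  expect_identical(classify_profile(pure), "central_peak_monotonic")
  gm <- grand_mean_model()
  expect_identical(classify_profile(gm), "shoulder")
  ring <- m3g(N = c(0.05, 0.4, 0), q = c(30, 3, 1), g = c(0, 0.8, 0))
  expect_identical(classify_profile(ring), "eccentric_peak")
})

test_that("derive_all assembles consistent derived parameters", {
  gm <- grand_mean_model()
  d <- derive_all(gm)
  expect_equal(d$A0, predict(gm, 0))
  expect_equal(d$A_ecc, predict(gm, d$critical_points$dd4))
  expect_lte(d$AUC02, d$AUC5)
  expect_true(d$monotonic)
  expect_identical(d$profile_class, "shoulder")
  # a monotone single-component profile has no eccentric peak
  mono <- m3g(N = c(0.5, 0, 0), q = c(3, 1, 1), g = c(0, 0, 0))
  dm <- derive_all(mono)
  expect_true(dm$monotonic)
  expect_true(is.na(dm$A_ecc))
  expect_identical(dm$profile_class, "central_peak_monotonic")
  # a dominant eccentric component breaks monotonicity
  ecc <- m3g(N = c(0.05, 0.5, 0), q = c(30, 3, 1), g = c(0, 0.7, 0))
  expect_false(derive_all(ecc)$monotonic)
})

test_that("pigment volumes increase with radius and match quadrature", {
  gm <- grand_mean_model()
  v <- vapply(c(0.2, 1, 2, 3), function(r) model_volume(gm, r), numeric(1))
  expect_true(all(diff(v) > 0))
  quad <- 2 * pi * stats::integrate(function(r) predict(gm, r) * r, 0, 2,
                                    rel.tol = 1e-12)$value
  expect_equal(model_volume(gm, 2), quad, tolerance = 1e-8)
})
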