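test_that("cohort sampling is deterministic per seed", {
  s <- cohort_spec(n_eyes = 12, seed = 99)
  c1 <- sample_cohort(s)
  c2 <- sample_cohort(s)
  expect_identical(c1, c2)
  c3 <- sample_cohort(cohort_spec(n_eyes = 12, seed = 100))
  expect_false(identical(c1$true_N1, c3$true_N1))
})

test_that("sampled parameters reproduce the truncated-normal moments", {
  co <- big_cohort()
  spec <- attr(co, "spec")
  b <- spec$bounds
  # analytic truncated-normal moment oracle
  tn_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; z <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(z)) /
      (stats::pnorm(z) - stats::pnorm(a))
  }
  n <- nrow(co)
  for (k in c("N1", "N2", "q2", "g2", "q3")) {
    mu <- spec$param_means[[k]]; sd <- spec$param_sds[[k]]
    m_exp <- tn_mean(mu, sd, b$lower[[k]], b$upper[[k]])
    se <- sd / sqrt(n)   # conservative: truncation shrinks the variance
    expect_lt(abs(mean(co[[paste0("true_", k)]]) - m_exp), 3 * se,
              label = paste("mean of", k))
  }
  # N1 barely feels its truncation, so its sample mean sits close to the
  # nominal population value too
  expect_equal(mean(co$true_N1), 0.224, tolerance = 0.02)
  expect_true(all(co$true_q1 >= b$lower[["q1"]] &
                    co$true_q1 <= b$upper[["q1"]]))
})

test_that("morphometry distributions and invariants hold", {
  co <- big_cohort()
  expect_equal(mean(co$FAZer), 0.91, tolerance = 0.02)
  expect_equal(sd(co$FAZer), 0.19, tolerance = 0.02)
  expect_equal(mean(co$bwlht), 123, tolerance = 0.02)
  expect_equal(mean(co$Pr), 3.96, tolerance = 0.02)
  expect_true(all(co$FAZer <= co$FAZf))
  # FAZ metrics are nearly collinear, as in measured cohorts
  expect_gt(cor(co$FAZf, co$FAZer), 0.95)
})

test_that("the dd6-morphometry linkage attains the target R-squared", {
  co <- big_cohort()
  cc <- co[!is.na(co$dd6), ]
  fit <- multiple_regression(cc, "dd6", c("FAZer", "bwlht", "Pr"))
  expect_equal(fit$r2, 0.81, tolerance = 0.02)
  expect_equal(unname(fit$betas),
               c(0.605, 0.426, 0.190), tolerance = 0.05)
})

test_that("target R-squared of 1 makes dd6 an exact linear combination", {
  co <- sample_cohort(cohort_spec(n_eyes = 60, target_r2 = 1, seed = 3))
  cc <- co[!is.na(co$dd6), ]
  spec <- attr(co, "spec")
  Xs <- sweep(sweep(as.matrix(cc[, c("FAZer", "bwlht", "Pr")]), 2,
                    spec$morph_means[c("FAZer", "bwlht", "Pr")]), 2,
              spec$morph_sds[c("FAZer", "bwlht", "Pr")], "/")
  z <- (cc$dd6 - mean(cc$dd6)) / sd(cc$dd6)
  expect_equal(as.numeric(Xs %*% c(0.605, 0.426, 0.190)), z,
               tolerance = 1e-6)
})

test_that("rendered profiles carry the requested noise", {
  gm <- grand_mean_model()
  p0 <- render_profile(gm, noise_sd = 0)
  expect_equal(p0$mpod, predict(gm, p0$ecc))
  grid <- seq(0.01, 5, length.out = 1e5)
  p <- render_profile(gm, grid = grid, noise_sd = 0.01, seed = 12)
  expect_equal(sd(p$mpod - predict(gm, grid)), 0.01, tolerance = 0.02)
  p1 <- render_profile(gm, noise_sd = 0.01, seed = 4)
  p2 <- render_profile(gm, noise_sd = 0.01, seed = 4)
  expect_identical(p1$mpod, p2$mpod)
  expect_error(render_profile(gm, noise_sd = -1), "non-negative")
})

test_that("rendered maps are deterministic and radially faithful", {
  gm <- grand_mean_model()
  m1 <- render_map(gm, size_px = 201, scale = 0.05, noise_sd = 0.01,
                   seed = 8)
  m2 <- render_map(gm, size_px = 201, scale = 0.05, noise_sd = 0.01,
                   seed = 8)
  expect_identical(m1$pixels, m2$pixels)
  # a single huge-spread component renders a constant image
  flat <- m3g(N = c(0.3, 0, 0), q = c(1e-10, 1, 1), g = c(0, 0, 0))
  mf <- render_map(flat, size_px = 101, scale = 0.05, noise_sd = 0)
  expect_equal(max(mf$pixels) - min(mf$pixels), 0, tolerance = 1e-8)
})

test_that("fit and derive recover dd6 from rendered noisy profiles", {
  co <- sample_cohort(cohort_spec(n_eyes = 50, noise_sd = 0.005,
                                  seed = 77))
  err <- vapply(seq_len(nrow(co)), function(i) {
    p <- render_profile(cohort_model(co, i), noise_sd = 0.005,
                        seed = 1000 + i)
    f <- tryCatch(fit_mpod(p, "m3g", window = c(0, 5)),
                  mpod_nonconvergence = function(e) e$fit)
    dd6_hat <- critical_points(f)$dd6
    abs(dd6_hat - co$dd6[i])
  }, numeric(1))
  expect_lt(median(err, na.rm = TRUE), 0.02)
})

test_that("infeasible cohort specifications are rejected", {
  expect_error(cohort_spec(n_eyes = 0), "n_eyes")
  means <- c(N1 = 5, N2 = 0.296, N3 = 0.097,
             q1 = 32.092, q2 = 1.938, q3 = -0.009,
             g1 = -0.027, g2 = 0.547, g3 = 5.345)
  expect_error(cohort_spec(param_means = means, param_sds =
    c(N1 = 0.01, N2 = 0.125, N3 = 0.092, q1 = 43.978, q2 = 0.792,
      q3 = 0.032, g1 = 0.067, g2 = 0.265, g3 = 5.243)),
    "infeasible truncation")
  expect_error(cohort_spec(target_r2 = 0), "target_r2")
})
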