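test_that("perfect collinearity loads two variables onto one factor", {
  set.seed(5)
  v1 <- rnorm(60)
  d <- data.frame(v1 = v1, v2 = v1, v3 = rnorm(60))
  fa <- factor_analysis(d, c("v1", "v2", "v3"), n_factors = 2)
  expect_gt(abs(fa$loadings["v1", 1]), 0.98)
  expect_gt(abs(fa$loadings["v2", 1]), 0.98)
  expect_lt(abs(fa$loadings["v3", 1]), 0.3)
  expect_gt(abs(fa$loadings["v3", 2]), 0.9)
})

test_that("highly correlated FAZ-like metrics collapse onto one factor", {
  set.seed(8)
  n <- 200
  u <- rnorm(n)
  lam <- sqrt(0.98)
  d <- data.frame(a = lam * u + sqrt(1 - 0.98) * rnorm(n),
                  b = lam * u + sqrt(1 - 0.98) * rnorm(n),
                  c = lam * u + sqrt(1 - 0.98) * rnorm(n))
  fa <- factor_analysis(d, c("a", "b", "c"))
  expect_identical(ncol(fa$loadings), 1L)
  expect_gt(fa$variance_explained[1], 0.97)
  expect_true(all(fa$significant[, 1]))
})

test_that("orthogonal variables produce no spurious shared loadings", {
  # with uncorrelated variables the eigenvalues are near-degenerate and the
  # unrotated axes are arbitrary, so simple structure is judged after
  # varimax: independent standard normals should essentially never put two
  # variables significantly on one factor
  set.seed(13)
  shared <- vapply(1:100, function(i) {
    d <- as.data.frame(matrix(rnorm(200 * 3), ncol = 3,
                              dimnames = list(NULL, c("x", "y", "z"))))
    fa <- factor_analysis(d, c("x", "y", "z"), n_factors = 3,
                          rotate = "varimax")
    any(colSums(fa$significant) >= 2)
  }, logical(1))
  expect_lt(mean(shared), 0.05)
})

test_that("full principal-components loadings reproduce the correlation
           matrix", {
  co <- sample_cohort(cohort_spec(n_eyes = 48, seed = 2),
                      include_summaries = TRUE)
  vars <- c("FAZf", "FAZm", "FAZer", "bwlht", "Pr", "ODrad02", "ODrad1",
            "Peak")
  fa <- factor_analysis(co, vars, n_factors = length(vars))
  R <- cor(co[, vars])
  expect_equal(fa$loadings_full %*% t(fa$loadings_full),
               unclass(R), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(abs(fa$loadings) <= 1 + 1e-8))
  expect_true(all(diff(fa$eigenvalues) <= 1e-12))
})

test_that("degenerate and invalid factor inputs raise clear errors", {
  d <- data.frame(a = rep(1, 10), b = rnorm(10))
  expect_error(factor_analysis(d, c("a", "b")), "a")
  expect_error(factor_analysis(d, c("a", "nope")), "nope")
  expect_error(factor_analysis(d[1:2, ], c("a", "b")), "3 complete rows")
})

test_that("multiple regression recovers exact standardized coefficients", {
  # standardized betas equal the generating coefficients only if the
  # response has unit variance, which pins down the predictor
  # correlations: b' S b = 1 with equicorrelation rho
  set.seed(19)
  n <- 200
  b <- c(0.605, 0.426, 0.190)
  rho <- (1 - sum(b^2)) /
    (2 * (b[1] * b[2] + b[1] * b[3] + b[2] * b[3]))
  S <- matrix(rho, 3, 3); diag(S) <- 1
  W <- scale(matrix(rnorm(n * 3), ncol = 3), scale = FALSE)
  Q <- qr.Q(qr(W)) * sqrt(n - 1)   # exactly uncorrelated, unit sample sd
  Z <- Q %*% chol(S)               # exact sample correlation S
  d <- data.frame(y = as.numeric(Z %*% b),
                  x1 = Z[, 1], x2 = Z[, 2], x3 = Z[, 3])
  fit <- suppressWarnings(multiple_regression(d, "y", c("x1", "x2", "x3")))
  expect_equal(unname(fit$betas), b, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_true(fit$useful)
})

test_that("an uninformative predictor set gives near-zero R-squared", {
  set.seed(29)
  d <- data.frame(y = rnorm(2000), x1 = rnorm(2000), x2 = rnorm(2000))
  fit <- multiple_regression(d, "y", c("x1", "x2"))
  expect_lt(fit$r2, 0.01)
  expect_false(fit$useful)
})

test_that("collinear designs are rejected", {
  set.seed(37)
  d <- data.frame(y = rnorm(30), x1 = rnorm(30))
  d$x2 <- d$x1
  expect_error(multiple_regression(d, "y", c("x1", "x2")), "collinear")
})

test_that("forward stepwise selects by marginal contribution and its
           increments telescope", {
  set.seed(41)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 1.0 * x1 + 0.4 * x2 + 0.15 * x3 + rnorm(n, 0, 0.5)
  d <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
  sw <- stepwise_forward(d, "y", c("x3", "x2", "x1"))
  expect_identical(sw$selected_order, c("x1", "x2", "x3"))
  expect_equal(sum(sw$stepwise_r2_increments), sw$r2, tolerance = 1e-12)
  expect_true(all(diff(sw$stepwise_r2_increments) < 0))
})

test_that("stepwise keeps only informative predictors and honours
           alpha_enter", {
  # the informative predictor always enters first; pure-noise candidates
  # enter only at roughly the alpha_enter false-positive rate
  set.seed(43)
  res <- vapply(1:40, function(i) {
    n <- 500
    x1 <- rnorm(n)
    d <- data.frame(y = x1 + rnorm(n, 0, 0.3), x1 = x1,
                    noise1 = rnorm(n), noise2 = rnorm(n))
    sw <- stepwise_forward(d, "y", c("x1", "noise1", "noise2"))
    c(first_ok = sw$selected_order[1] == "x1",
      extra = length(sw$selected_order) > 1L)
  }, logical(2))
  expect_true(all(res["first_ok", ]))
  expect_lt(mean(res["extra", ]), 0.2)
  d0 <- data.frame(y = rnorm(50), x1 = rnorm(50), noise1 = rnorm(50))
  none <- stepwise_forward(d0, "y", c("x1", "noise1"), alpha_enter = 0)
  expect_length(none$selected_order, 0)
  expect_identical(none$r2, 0)
})

test_that("eyes missing a derived feature drop listwise", {
  co <- sample_cohort(cohort_spec(n_eyes = 200, seed = 55))
  expect_gt(sum(is.na(co$dd6)), 0)
  fit <- multiple_regression(co, "dd6", c("FAZer", "bwlht", "Pr"))
  expect_identical(fit$n_used, sum(!is.na(co$dd6)))
})
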