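# Shared fixtures for the test suite.

# Grand-mean three-Gaussian parameters of the reference cohort (printed to
# 3 dp), and the derived values published alongside them.
grand_mean_model <- function() {
  m3g(N = c(0.200, 0.250, 0.039),
      q = c(14.515, 1.700, -0.020),
      g = c(-0.017, 0.562, 10.000))
}

printed_grand_mean <- list(
  dd = c(dd1 = 0.175, dd2 = 0.296, dd3 = 0.502, dd4 = 0.687,
         dd5 = 1.086, dd6 = 1.497),
  HHr = 1.177, A0 = 0.649, A_ecc = 0.475, AUC02 = 0.125, AUC5 = 1.048)

# Population-mean parameters of the fitted cohort distribution.
cohort_mean_model <- function() {
  m3g(N = c(0.224, 0.296, 0.097),
      q = c(32.092, 1.938, -0.009),
      g = c(-0.027, 0.547, 5.345))
}

# random in-bounds three-Gaussian parameter draw (uniform over the default
# fitting box)
random_m3g <- function() {
  b <- default_bounds("m3g")
  p <- b$lower + runif(9) * (b$upper - b$lower)
  names(p) <- names(b$lower)
  m3g(N = p[1:3], q = p[4:6], g = p[7:9])
}

# one large default-spec cohort, drawn once and reused across tests
big_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sample_cohort(cohort_spec(n_eyes = 10000, seed = 42))
    cache
  }
})

# central finite differences on the model curve: the derivative oracle.
# The second difference uses a larger step because its rounding error
# grows as 1/h^2; 5e-5 balances rounding against truncation.
fd_deriv <- function(model, x, order, h = if (order == 1) 1e-5 else 5e-5) {
  f <- function(x) predict(model, x)
  if (order == 1) (f(x + h) - f(x - h)) / (2 * h)
  else (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}
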