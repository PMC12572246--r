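#' Principal-components factor analysis with a loading threshold
#'
#' Variable-reduction step of the cohort workflow: principal-components
#' extraction on the correlation matrix of the chosen variables. Loadings
#' are eigenvectors scaled by the square root of their eigenvalues (so they
#' are variable-factor correlations); factors are retained by the Kaiser
#' rule (eigenvalue > 1) unless `n_factors` is given, and loadings with
#' absolute value above `threshold` are flagged significant. No rotation is
#' applied by default; varimax is available.
#'
#' Rows with missing values in the chosen variables are dropped listwise.
#'
#' @param data a data frame.
#' @param variables character vector of numeric column names.
#' @param n_factors optional fixed number of retained factors.
#' @param threshold absolute-loading significance threshold.
#' @param rotate `"none"` (default) or `"varimax"` (applied to the retained
#'   factors).
#' @return An object of class `mpod_factor`: retained `loadings`
#'   (variables x factors), `variance_explained` (fraction per retained
#'   factor), `significant` (logical mask), `eigenvalues`, `loadings_full`,
#'   `n_used`.
#' @export
factor_analysis <- function(data, variables, n_factors = NULL,
                            threshold = 0.7,
                            rotate = c("none", "varimax")) {
  rotate <- match.arg(rotate)
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop("variables not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- data[, variables, drop = FALSE]
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all variables must be numeric", call. = FALSE)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 complete rows", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant (degenerate) variable: ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L_full <- e$vectors %*% diag(sqrt(ev), length(ev))
  dimnames(L_full) <- list(variables, paste0("F", seq_along(ev)))
  k <- if (is.null(n_factors)) max(sum(e$values > 1), 1L)
       else as.integer(n_factors)
  L <- L_full[, seq_len(k), drop = FALSE]
  if (rotate == "varimax" && k > 1L) {
    rot <- stats::varimax(L, normalize = FALSE)
    L <- L %*% rot$rotmat
    dimnames(L) <- list(variables, paste0("F", seq_len(k)))
  }
  # sign convention: dominant loading of each factor positive
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  ve <- colSums(L^2) / length(variables)
  structure(list(loadings = L, variance_explained = ve,
                 significant = abs(L) > threshold,
                 threshold = threshold,
                 eigenvalues = e$values, loadings_full = L_full,
                 n_used = nrow(X), rotate = rotate),
            class = "mpod_factor")
}

#' @export
print.mpod_factor <- function(x, digits = 2, ...) {
  cat("principal-components factor analysis:",
      ncol(x$loadings), "retained factor(s),",
      x$n_used, "rows", if (x$rotate != "none") paste0("(", x$rotate, ")"),
      "\n")
  cat("variance explained:",
      paste0(round(100 * x$variance_explained), "%", collapse = " "),
      "\n")
  L <- round(x$loadings, digits)
  mark <- ifelse(x$significant, "*", " ")
  out <- matrix(paste0(format(L), mark), nrow = nrow(L),
                dimnames = dimnames(L))
  print(out, quote = FALSE)
  cat("* |loading| >", x$threshold, "\n")
  invisible(x)
}

.standardize_frame <- function(data, vars) {
  X <- data[, vars, drop = FALSE]
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all regression variables must be numeric", call. = FALSE)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  Z <- as.data.frame(lapply(X, function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("constant variable in regression", call. = FALSE)
    (v - mean(v)) / s
  }))
  Z
}

#' Multiple regression on standardized variables
#'
#' Ordinary least squares of a response on a set of predictors, all
#' z-scored, reporting standardized slopes (beta), their p-values and the
#' coefficient of determination. Fits explaining less than half of the
#' response variance are flagged as unlikely to be useful for prediction
#' (`useful = FALSE`).
#'
#' @param data a data frame; rows with missing values among the used columns
#'   are dropped listwise.
#' @param y response column name.
#' @param predictors character vector of predictor column names.
#' @return An object of class `mpod_regression` with `betas`, `se`,
#'   `p_values`, `r2`, `useful`, `n_used`.
#' @export
multiple_regression <- function(data, y, predictors) {
  vars <- c(y, predictors)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variables not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  Z <- .standardize_frame(data, vars)
  n <- nrow(Z)
  if (n <= length(predictors) + 1L)
    stop("need more rows than predictors + 1", call. = FALSE)
  M <- as.matrix(Z[, predictors, drop = FALSE])
  if (qr(cbind(1, M))$rank < ncol(M) + 1L)
    stop("rank-deficient (collinear) design", call. = FALSE)
  fit <- stats::lm(Z[[y]] ~ M)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  betas <- co[, 1]; names(betas) <- predictors
  se <- co[, 2]; names(se) <- predictors
  pv <- co[, 4]; names(pv) <- predictors
  structure(list(betas = betas, se = se, p_values = pv,
                 r2 = sm$r.squared, useful = sm$r.squared >= 0.5,
                 n_used = n, y = y, method = "multiple"),
            class = "mpod_regression")
}

#' Forward stepwise regression on standardized variables
#'
#' Greedy forward selection: at each step the candidate with the largest
#' F-to-enter joins the model provided its partial F test has
#' `p < alpha_enter`. Records the entry order and the increment in R^2
#' contributed by each selected predictor (increments telescope to the
#' final R^2).
#'
#' @inheritParams multiple_regression
#' @param candidates character vector of candidate predictor names.
#' @param alpha_enter entry significance level; 0 selects nothing.
#' @return An `mpod_regression` with `selected_order` and
#'   `stepwise_r2_increments`; `betas`/`r2` describe the final selected
#'   model (empty selection gives `r2 = 0`).
#' @export
stepwise_forward <- function(data, y, candidates, alpha_enter = 0.05) {
  vars <- c(y, candidates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variables not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  Z <- .standardize_frame(data, vars)
  n <- nrow(Z)
  if (n <= length(candidates) + 1L)
    stop("need more rows than candidates + 1", call. = FALSE)
  yv <- Z[[y]]
  selected <- character(0)
  increments <- numeric(0)
  r2 <- 0
  rss <- function(vars) {
    if (!length(vars)) return(sum((yv - mean(yv))^2))
    M <- as.matrix(Z[, vars, drop = FALSE])
    sum(stats::lm.fit(cbind(1, M), yv)$residuals^2)
  }
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    rss0 <- rss(selected)
    cand_stats <- vapply(remaining, function(v) {
      rss1 <- rss(c(selected, v))
      df2 <- n - length(selected) - 2L
      f <- (rss0 - rss1) / (rss1 / df2)
      c(f = f, p = stats::pf(f, 1, df2, lower.tail = FALSE), rss1 = rss1)
    }, numeric(3))
    best <- which.max(cand_stats["f", ])
    if (!(cand_stats["p", best] < alpha_enter)) break
    v <- remaining[best]
    tss <- sum((yv - mean(yv))^2)
    new_r2 <- 1 - cand_stats["rss1", best] / tss
    increments <- c(increments, stats::setNames(new_r2 - r2, v))
    r2 <- new_r2
    selected <- c(selected, v)
  }
  betas <- stats::setNames(numeric(0), character(0))
  pv <- betas; se <- betas
  if (length(selected)) {
    fin <- multiple_regression(data, y, selected)
    betas <- fin$betas; pv <- fin$p_values; se <- fin$se
  }
  structure(list(betas = betas, se = se, p_values = pv, r2 = r2,
                 useful = r2 >= 0.5, n_used = n, y = y,
                 selected_order = selected,
                 stepwise_r2_increments = increments,
                 alpha_enter = alpha_enter, method = "stepwise-forward"),
            class = "mpod_regression")
}

#' @export
print.mpod_regression <- function(x, digits = 3, ...) {
  cat(x$method, "regression of", x$y, "(standardized), n =", x$n_used, "\n")
  if (length(x$betas)) {
    tab <- cbind(beta = x$betas, se = x$se, p = x$p_values)
    print(round(tab, digits))
  } else cat("  (no predictors selected)\n")
  cat("R^2 =", round(x$r2, digits),
      if (!x$useful) "(below the 50% usefulness bar)", "\n")
  if (!is.null(x$selected_order) && length(x$selected_order))
    cat("entry order:", paste(x$selected_order, collapse = " -> "),
        "; R^2 increments:",
        paste(round(x$stepwise_r2_increments, digits), collapse = ", "),
        "\n")
  invisible(x)
}
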