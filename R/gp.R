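# Gaussian-process regression with fixed per-point (heteroscedastic) noise,
# evidence maximization, and posterior function sampling. Three covariance
# families are provided: squared exponential (smoothly fluctuating samples),
# linear (straight lines through the origin), and the neural-network kernel of
# Williams, whose samples have a sigmoid-like shape; kernels can be summed.

#' Covariance kernel constructors
#'
#' Build kernel specifications for [gp_fit()]. Hyperparameters are stored on
#' their natural (positive) scale; optimization happens internally in log
#' space.
#'
#' Parameterizations, for inputs `x`, `x'`:
#' \describe{
#'   \item{squared exponential}{`k(x, x') = amplitude^2 exp(-(x - x')^2 / (2 lengthscale^2))`}
#'   \item{linear}{`k(x, x') = variance * x * x'`}
#'   \item{neural network}{`k(x, x') = amplitude^2 (2/pi) asin( 2 (scale0^2 + scale1^2 x x') /
#'     sqrt((1 + 2 (scale0^2 + scale1^2 x^2)) (1 + 2 (scale0^2 + scale1^2 x'^2))) )`}
#' }
#'
#' @param amplitude,lengthscale,variance,scale0,scale1 Strictly positive
#'   hyperparameters (see parameterizations above).
#' @param a,b Two kernels to sum.
#' @return An object of class `gp_kernel`.
#' @examples
#' k <- kernel_sum(kernel_sqexp(1, 0.3), kernel_linear(0.5))
#' kernel_matrix(k, c(0, 0.5, 1))
#' @name kernels
NULL

new_kernel <- function(family, hyperparams, children = NULL) {
  if (any(hyperparams <= 0) || any(!is.finite(hyperparams))) {
    stop_platemix("kernel hyperparameters must be strictly positive and finite",
                  "platemix_domain_error")
  }
  structure(list(family = family, hyperparams = hyperparams,
                 children = children),
            class = "gp_kernel")
}

#' @rdname kernels
#' @export
kernel_sqexp <- function(amplitude = 1, lengthscale = 1) {
  new_kernel("squared_exponential",
             c(amplitude = amplitude, lengthscale = lengthscale))
}

#' @rdname kernels
#' @export
kernel_linear <- function(variance = 1) {
  new_kernel("linear", c(variance = variance))
}

#' @rdname kernels
#' @export
kernel_nn <- function(amplitude = 1, scale0 = 1, scale1 = 1) {
  new_kernel("neural_network",
             c(amplitude = amplitude, scale0 = scale0, scale1 = scale1))
}

#' @rdname kernels
#' @export
kernel_sum <- function(a, b) {
  stopifnot(inherits(a, "gp_kernel"), inherits(b, "gp_kernel"))
  structure(list(family = "sum", hyperparams = numeric(0), children = list(a, b)),
            class = "gp_kernel")
}

#' @export
print.gp_kernel <- function(x, ...) {
  cat("<gp_kernel>", kernel_describe(x), "\n")
  invisible(x)
}

kernel_describe <- function(k) {
  if (k$family == "sum") {
    paste(kernel_describe(k$children[[1]]), "+", kernel_describe(k$children[[2]]))
  } else {
    paste0(k$family, "(",
           paste(sprintf("%s=%.4g", names(k$hyperparams), k$hyperparams),
                 collapse = ", "), ")")
  }
}

# Flatten hyperparameters of (possibly summed) kernels into one vector and
# rebuild a kernel from such a vector; used by the optimizer.
kernel_pack <- function(k) {
  if (k$family == "sum") {
    c(kernel_pack(k$children[[1]]), kernel_pack(k$children[[2]]))
  } else {
    unname(k$hyperparams)
  }
}

kernel_unpack <- function(k, theta) {
  if (k$family == "sum") {
    n1 <- length(kernel_pack(k$children[[1]]))
    k$children[[1]] <- kernel_unpack(k$children[[1]], theta[seq_len(n1)])
    k$children[[2]] <- kernel_unpack(k$children[[2]], theta[-seq_len(n1)])
    k
  } else {
    k$hyperparams[] <- theta
    k
  }
}

#' Evaluate a covariance matrix
#'
#' @param kernel A `gp_kernel`.
#' @param x1 Numeric vector of inputs (rows).
#' @param x2 Numeric vector of inputs (columns); defaults to `x1`.
#' @return A `length(x1)` by `length(x2)` covariance matrix.
#' @export
kernel_matrix <- function(kernel, x1, x2 = x1) {
  assert_numeric(x1, "x1"); assert_numeric(x2, "x2")
  h <- kernel$hyperparams
  switch(kernel$family,
    squared_exponential = {
      d <- outer(x1, x2, "-")
      h[["amplitude"]]^2 * exp(-d^2 / (2 * h[["lengthscale"]]^2))
    },
    linear = h[["variance"]] * outer(x1, x2),
    neural_network = {
      s0 <- h[["scale0"]]^2; s1 <- h[["scale1"]]^2
      num <- 2 * (s0 + s1 * outer(x1, x2))
      den <- sqrt(outer(1 + 2 * (s0 + s1 * x1^2), 1 + 2 * (s0 + s1 * x2^2)))
      # clamp guards asin against rounding just past +/-1 when x1 == x2
      h[["amplitude"]]^2 * (2 / pi) * asin(pmin(pmax(num / den, -1), 1))
    },
    sum = kernel_matrix(kernel$children[[1]], x1, x2) +
          kernel_matrix(kernel$children[[2]], x1, x2),
    stop_platemix(sprintf("unknown kernel family '%s'", kernel$family),
                  "platemix_domain_error")
  )
}

# Cholesky with escalating jitter: factorize exactly if possible, otherwise
# add 1e-9 x mean diagonal and multiply by 10 until success, giving up at
# 1e-3 x mean diagonal.
chol_jitter <- function(K, start = 1e-9, max_rel = 1e-3) {
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(L)) return(list(L = L, jitter = 0))
  scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- start * scale
  repeat {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    jit <- jit * 10
    if (jit > max_rel * scale) {
      stop_platemix("covariance matrix not positive definite even after jitter",
                    "platemix_numerical_error")
    }
  }
}

# Log marginal likelihood of y under a zero-mean GP with covariance
# K + diag(noise_sd^2); the central quantity maximized by gp_fit.
gp_log_marginal <- function(kernel, x, y, noise_sd) {
  K <- kernel_matrix(kernel, x) + diag(noise_sd^2, length(x))
  cj <- chol_jitter(K)
  L <- cj$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  ll <- -0.5 * sum(y * alpha) - sum(log(diag(L))) -
    0.5 * length(y) * log(2 * pi)
  list(log_lik = ll, L = L, alpha = alpha, jitter = cj$jitter)
}

#' Fit a Gaussian process by maximizing the marginal likelihood
#'
#' Fits a zero-mean Gaussian process to `(x, y)` with Gaussian,
#' independent-per-point measurement noise. Noise standard deviations may be
#' supplied per point (heteroscedastic, e.g. from [empirical_noise()]) or
#' learned as a single constant scale jointly with the kernel hyperparameters
#' (`noise_sd = "learn"`). Hyperparameters are optimized in log space with
#' bounded quasi-Newton (L-BFGS-B) from several deterministic starting points;
#' the best converged restart is kept.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @param noise_sd Positive numeric vector (length 1 or `length(x)`), or the
#'   string `"learn"`.
#' @param kernel A `gp_kernel` giving the covariance family and the initial
#'   hyperparameters.
#' @param optimize If `FALSE`, keep the supplied hyperparameters and only
#'   compute the posterior and the log evidence (useful for checking the
#'   marginal likelihood against direct evaluation).
#' @param restarts Number of deterministic restarts (scale multiplier ladder).
#' @return A `gp_posterior` with elements `x`, `y`, `noise_sd`, `kernel`
#'   (optimized), `log_evidence`, `noise_mode` (`"fixed"` or `"learned"`) and
#'   the cached Cholesky factorization.
#' @seealso [gp_predict()], [gp_sample()]
#' @export
gp_fit <- function(x, y, noise_sd, kernel, optimize = TRUE, restarts = 5) {
  assert_numeric(x, "x"); assert_numeric(y, "y")
  if (length(x) != length(y) || length(x) < 2) {
    stop_platemix("x and y must have equal length >= 2", "platemix_domain_error")
  }
  stopifnot(inherits(kernel, "gp_kernel"))
  learn_noise <- identical(noise_sd, "learn")
  if (!learn_noise) {
    assert_numeric(noise_sd, "noise_sd")
    if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, length(x))
    if (length(noise_sd) != length(x) || any(noise_sd <= 0)) {
      stop_platemix("noise_sd must be positive, length 1 or length(x)",
                    "platemix_domain_error")
    }
  }

  base <- kernel_pack(kernel)
  n_kern <- length(base)
  noise0 <- if (learn_noise) max(stats::sd(y) / 10, 1e-6) else NULL

  make_fit <- function(theta) {
    k <- kernel_unpack(kernel, exp(theta[seq_len(n_kern)]))
    ns <- if (learn_noise) rep(exp(theta[n_kern + 1]), length(x)) else noise_sd
    lm <- gp_log_marginal(k, x, y, ns)
    list(kernel = k, noise_sd = ns, lm = lm)
  }

  if (!optimize) {
    theta0 <- log(c(base, noise0))
    f <- make_fit(theta0)
    return(new_gp_posterior(x, y, f, learn_noise))
  }

  neg_ll <- function(theta) {
    val <- tryCatch(-make_fit(theta)$lm$log_lik, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  # deterministic restart ladder: all hyperparameters scaled together
  mults <- c(1, 0.3, 3, 0.1, 10)[seq_len(max(1, restarts))]
  theta_base <- log(c(base, noise0))
  best <- NULL
  best_val <- Inf
  any_conv <- FALSE
  for (m in mults) {
    th0 <- theta_base + log(m)
    opt <- tryCatch(
      stats::optim(th0, neg_ll, method = "L-BFGS-B",
                   lower = theta_base - 12, upper = theta_base + 12,
                   control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.finite(opt$value) && opt$value < best_val) {
      best_val <- opt$value
      best <- opt
    }
  }
  if (is.null(best) || !any_conv || !is.finite(best_val) || best_val >= 1e10) {
    state <- if (!is.null(best)) tryCatch(make_fit(best$par), error = function(e) NULL)
    stop_platemix("GP hyperparameter optimization failed to converge",
                  "platemix_fit_error", best_state = state)
  }
  f <- make_fit(best$par)
  new_gp_posterior(x, y, f, learn_noise)
}

new_gp_posterior <- function(x, y, f, learn_noise) {
  structure(list(
    x = x, y = y,
    noise_sd = f$noise_sd,
    kernel = f$kernel,
    log_evidence = f$lm$log_lik,
    noise_mode = if (learn_noise) "learned" else "fixed",
    L = f$lm$L, alpha = f$lm$alpha, jitter = f$lm$jitter
  ), class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat("<gp_posterior>", length(x$x), "points;",
      kernel_describe(x$kernel), "\n",
      sprintf(" log evidence %.3f; noise %s\n", x$log_evidence, x$noise_mode))
  invisible(x)
}

#' Posterior mean and standard deviation at new inputs
#'
#' @param post A fitted `gp_posterior`.
#' @param x_star Numeric vector of query inputs.
#' @return A list with numeric vectors `mean` and `sd` (pointwise posterior
#'   standard deviation of the latent function, excluding measurement noise).
#' @export
gp_predict <- function(post, x_star) {
  stopifnot(inherits(post, "gp_posterior"))
  assert_numeric(x_star, "x_star")
  ks <- kernel_matrix(post$kernel, post$x, x_star)
  mu <- drop(crossprod(ks, post$alpha))
  v <- forwardsolve(t(post$L), ks)
  kss <- diag(kernel_matrix(post$kernel, x_star))
  var <- pmax(kss - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(var))
}

#' Draw sample functions from a GP posterior
#'
#' @param post A fitted `gp_posterior`.
#' @param x_star Numeric vector of query inputs.
#' @param n Number of draws.
#' @param seed Integer seed; draws are reproducible and do not disturb the
#'   caller's RNG state.
#' @return A `length(x_star)` by `n` matrix; each column is one sampled
#'   function evaluated on `x_star`.
#' @export
gp_sample <- function(post, x_star, n, seed) {
  stopifnot(inherits(post, "gp_posterior"), n >= 1)
  assert_numeric(x_star, "x_star")
  ks <- kernel_matrix(post$kernel, post$x, x_star)
  mu <- drop(crossprod(ks, post$alpha))
  v <- forwardsolve(t(post$L), ks)
  cov <- kernel_matrix(post$kernel, x_star) - crossprod(v)
  cov <- (cov + t(cov)) / 2
  cl <- chol_jitter(cov)
  z <- with_seed(seed, matrix(stats::rnorm(length(x_star) * n), ncol = n))
  mu + crossprod(cl$L, z)
}

#' Empirical per-point noise from nearest neighbours
#'
#' Estimates a heteroscedastic measurement-error standard deviation at every
#' data point as the sample standard deviation (n - 1 denominator) of the `k`
#' points nearest in the input coordinate, including the point itself. Ties in
#' distance are broken by original index order. A floor of `1e-12` avoids zero
#' variances.
#'
#' @param x Numeric input coordinate (time or OD).
#' @param y Numeric responses, same length as `x`.
#' @param k Number of neighbours (2 <= k <= length(x)).
#' @return Positive numeric vector of per-point noise standard deviations.
#' @export
empirical_noise <- function(x, y, k) {
  assert_numeric(x, "x"); assert_numeric(y, "y")
  n <- length(x)
  if (length(y) != n) {
    stop_platemix("x and y must have equal length", "platemix_domain_error")
  }
  if (k < 2 || k > n) {
    stop_platemix("k must satisfy 2 <= k <= length(x)", "platemix_domain_error")
  }
  out <- vapply(seq_len(n), function(i) {
    idx <- order(abs(x - x[i]), seq_len(n))[seq_len(k)]
    stats::sd(y[idx])
  }, numeric(1))
  pmax(out, 1e-12)
}
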