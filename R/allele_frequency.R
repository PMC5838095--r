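#' Posterior distribution of the resistance allele frequency
#'
#' Builds the Bayesian posterior for the resistance allele frequency `q`
#' given an F2 screen with `s` true-positive lines out of `n` screened, each
#' line sampling `a` gametic haplotypes.
#'
#' Two conventions are supported:
#'
#' * `"beta_approx"` (default): a uniform prior on the line-carrying
#'   frequency `p` gives `p | s, n ~ Beta(s + 1, n - s + 1)`; for rare
#'   alleles `p = 1 - (1 - q)^a ~ a q`, so `q = p / a` with support
#'   `[0, 1/a]`. Closed form; reproduces the printed estimates.
#' * `"exact_numeric"`: a uniform prior directly on `q` in `[0, 1]` with the
#'   exact carrier likelihood, posterior density proportional to
#'   `(1 - (1-q)^a)^s (1-q)^(a (n-s))`, handled by adaptive quadrature.
#'
#' The linearisation behind `beta_approx` is accurate for `q` small relative
#' to `1/a`; the two conventions agree to about 2 significant figures when
#' `s << n`.
#'
#' @param s number of true-positive lines (S), or a [screen_count()].
#' @param n number of lines screened (N); ignored when `s` is a
#'   `screen_count`.
#' @param a gametic haplotypes per line (default 4).
#' @param method `"beta_approx"` or `"exact_numeric"`.
#' @return An object of class `posterior_q`.
#' @examples
#' post <- posterior_q(1, 137)
#' expected_q(post)                     # 0.0036
#' credibility_interval(post, 0.95)
#' @export
posterior_q <- function(s, n = NULL, a = 4L,
                        method = c("beta_approx", "exact_numeric")) {
  if (inherits(s, "screen_count")) {
    n <- s$n_lines
    s <- s$n_positive
  }
  s <- assert_count(s, "s", min = 0L)
  n <- assert_count(n, "n", min = 0L)
  if (s > n) stop_input("s cannot exceed n")
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 1) {
    stop_input("a (alleles per line) must be a number >= 1")
  }
  method <- match.arg(method)
  post <- structure(
    list(s = s, n = n, a = a, method = method,
         shape1 = s + 1, shape2 = n - s + 1),
    class = "posterior_q"
  )
  if (method == "exact_numeric") {
    kernel <- function(q) exact_log_kernel(q, s, n, a)
    z <- tryCatch(
      integrate(function(q) exp(kernel(q)), 0, 1,
                rel.tol = 1e-10, subdivisions = 500L),
      error = function(e) stop_numeric("posterior normalisation failed: ",
                                       conditionMessage(e))
    )
    if (z$value <= 0 || !is.finite(z$value)) {
      stop_numeric("posterior normalisation is degenerate (Z = ", z$value, ")")
    }
    post$log_z <- log(z$value)
  }
  post
}

# log of the unnormalised exact posterior kernel on q in [0, 1]
exact_log_kernel <- function(q, s, n, a) {
  out <- a * (n - s) * log1p(-q)
  if (s > 0) {
    lp <- ifelse(q <= 0, -Inf, log1p(-exp(a * log1p(-q))))
    out <- out + s * lp
  }
  out[q < 0 | q > 1] <- -Inf
  out
}

#' @export
print.posterior_q <- function(x, ...) {
  ci <- credibility_interval(x, 0.95)
  cat(sprintf(
    "Posterior for resistance allele frequency q (%s)\n", x$method))
  cat(sprintf("  S = %d positive lines of N = %d, a = %g alleles/line\n",
              x$s, x$n, x$a))
  cat(sprintf("  E(q) = %.4f, 95%% CI (%.4f, %.4f)\n",
              expected_q(x), ci[1L], ci[2L]))
  invisible(x)
}

#' Posterior expected resistance allele frequency E(q)
#'
#' @param posterior a [posterior_q()] object.
#' @return The posterior mean of `q`. Under the default beta convention this
#'   is `(s + 1) / ((n + 2) a)`.
#' @examples
#' round(expected_q(posterior_q(1, 137)), 4)  # 0.0036
#' @export
expected_q <- function(posterior) {
  check_posterior(posterior)
  if (posterior$method == "beta_approx") {
    return(posterior$shape1 / ((posterior$shape1 + posterior$shape2) *
                                 posterior$a))
  }
  num <- integrate(
    function(q) q * exp(exact_log_kernel(q, posterior$s, posterior$n,
                                         posterior$a) - posterior$log_z),
    0, 1, rel.tol = 1e-10, subdivisions = 500L
  )
  num$value
}

#' Equal-tailed credibility interval for the allele frequency
#'
#' @param posterior a [posterior_q()] object.
#' @param level posterior mass of the interval, in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`: the `(1 - level)/2` and
#'   `1 - (1 - level)/2` posterior quantiles of `q`.
#' @examples
#' round(credibility_interval(posterior_q(1, 137)), 4)
#' @export
credibility_interval <- function(posterior, level = 0.95) {
  check_posterior(posterior)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop_input("level must lie strictly between 0 and 1")
  }
  alpha <- (1 - level) / 2
  c(low = posterior_quantile(posterior, alpha),
    high = posterior_quantile(posterior, 1 - alpha))
}

#' Posterior density of the allele frequency
#'
#' @param posterior a [posterior_q()] object.
#' @param q allele frequency values (vectorised). Values outside the
#'   posterior support return density 0.
#' @return Density values.
#' @export
posterior_pdf <- function(posterior, q) {
  check_posterior(posterior)
  if (!is.numeric(q)) stop_input("q must be numeric")
  if (posterior$method == "beta_approx") {
    a <- posterior$a
    d <- ifelse(q >= 0 & q <= 1 / a,
                a * dbeta(pmin(q * a, 1), posterior$shape1, posterior$shape2),
                0)
    return(d)
  }
  ifelse(q >= 0 & q <= 1,
         exp(exact_log_kernel(q, posterior$s, posterior$n, posterior$a) -
               posterior$log_z),
         0)
}

#' Posterior cumulative distribution of the allele frequency
#'
#' @inheritParams posterior_pdf
#' @return `P(Q <= q)` for each element of `q`.
#' @export
posterior_cdf <- function(posterior, q) {
  check_posterior(posterior)
  if (!is.numeric(q)) stop_input("q must be numeric")
  if (posterior$method == "beta_approx") {
    return(pbeta(pmin(pmax(q * posterior$a, 0), 1),
                 posterior$shape1, posterior$shape2))
  }
  vapply(q, function(x) {
    if (x <= 0) return(0)
    if (x >= 1) return(1)
    integrate(function(u) exp(exact_log_kernel(u, posterior$s, posterior$n,
                                               posterior$a) - posterior$log_z),
              0, x, rel.tol = 1e-9, subdivisions = 500L)$value
  }, numeric(1))
}

#' Posterior quantile of the allele frequency
#'
#' @param posterior a [posterior_q()] object.
#' @param p probabilities in \[0, 1\] (vectorised).
#' @return Quantiles of `q`.
#' @export
posterior_quantile <- function(posterior, p) {
  check_posterior(posterior)
  assert_prob(p, "p")
  if (posterior$method == "beta_approx") {
    return(qbeta(p, posterior$shape1, posterior$shape2) / posterior$a)
  }
  vapply(p, function(pp) {
    if (pp <= 0) return(0)
    if (pp >= 1) return(1)
    uniroot(function(x) posterior_cdf(posterior, x) - pp,
            lower = 0, upper = 1, tol = 1e-12)$root
  }, numeric(1))
}

#' Draw samples from the posterior of the allele frequency
#'
#' @param posterior a [posterior_q()] object.
#' @param n_samples number of draws.
#' @param seed optional RNG seed (the caller's RNG stream is restored).
#' @return Numeric vector of sampled `q` values.
#' @export
posterior_sample <- function(posterior, n_samples, seed = NULL) {
  check_posterior(posterior)
  n_samples <- assert_count(n_samples, "n_samples", min = 1L)
  with_seed(seed, {
    if (posterior$method == "beta_approx") {
      rbeta(n_samples, posterior$shape1, posterior$shape2) / posterior$a
    } else {
      # inverse-CDF on a dense grid; the exact posterior is smooth and
      # unimodal so linear interpolation of the CDF suffices
      grid <- seq(0, 1, length.out = 4097L)
      cdf <- posterior_cdf(posterior, grid)
      approx(cdf, grid, xout = runif(n_samples), ties = "ordered",
             rule = 2)$y
    }
  })
}

check_posterior <- function(posterior) {
  if (!inherits(posterior, "posterior_q")) {
    stop_input("expected a posterior_q object")
  }
  invisible(posterior)
}
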