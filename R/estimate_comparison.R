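#' Probability that two campaigns' frequency estimates are equal
#'
#' Compares the posteriors of two monitoring campaigns through their joint
#' (independent) distribution. The two-sided probability of equality is
#' defined as `p = 2 * min(P(q_a < q_b), P(q_a > q_b))`: when the posteriors
#' coincide each half-plane holds mass 1/2 and `p ~ 1`; when they barely
#' overlap `p ~ 0`. Estimates are conventionally declared not statistically
#' different when `p > 0.05`. The raw half-plane masses are returned so
#' alternative two-sided definitions can be layered on top.
#'
#' @param post_a,post_b [posterior_q()] objects for the two campaigns.
#' @param method `"quadrature"` integrates `P(q_a < q_b) =
#'   \int F_a(x) f_b(x) dx`; `"monte_carlo"` draws paired posterior samples.
#' @param n_samples Monte-Carlo sample size (ignored for quadrature).
#' @param seed optional RNG seed for the Monte-Carlo method.
#' @return An object of class `prob_equal` with fields `p`, `p_a_less`,
#'   `p_a_greater`, `method` and (Monte-Carlo only) `mc_se`.
#' @examples
#' prob_equal(posterior_q(1, 137), posterior_q(0, 166))
#' @export
prob_equal <- function(post_a, post_b, method = c("quadrature", "monte_carlo"),
                       n_samples = 1e5, seed = NULL) {
  check_posterior(post_a)
  check_posterior(post_b)
  method <- match.arg(method)
  mc_se <- NA_real_
  if (method == "quadrature") {
    upper <- max(support_upper(post_a), support_upper(post_b))
    p_less <- integrate(
      function(x) posterior_cdf(post_a, x) * posterior_pdf(post_b, x),
      0, upper, rel.tol = 1e-9, subdivisions = 500L
    )$value
    p_less <- min(max(p_less, 0), 1)
    p_greater <- 1 - p_less  # continuous posteriors: P(q_a = q_b) = 0
  } else {
    n_samples <- assert_count(n_samples, "n_samples", min = 1L)
    draws <- with_seed(seed, {
      qa <- posterior_sample(post_a, n_samples)
      qb <- posterior_sample(post_b, n_samples)
      qa < qb
    })
    p_less <- mean(draws)
    p_greater <- 1 - p_less
    mc_se <- sqrt(p_less * p_greater / n_samples)
  }
  structure(
    list(p = min(2 * min(p_less, p_greater), 1),
         p_a_less = p_less, p_a_greater = p_greater,
         method = method, mc_se = mc_se),
    class = "prob_equal"
  )
}

support_upper <- function(posterior) {
  if (posterior$method == "beta_approx") 1 / posterior$a else 1
}

#' @export
print.prob_equal <- function(x, ...) {
  cat(sprintf(
    "P(estimates equal) = %.4f [%s]; P(q_a < q_b) = %.4f\n",
    x$p, x$method, x$p_a_less))
  cat(if (x$p > 0.05) "  -> not statistically different (p > 0.05)\n"
      else "  -> statistically different (p <= 0.05)\n")
  invisible(x)
}

#' What-if replication power for comparing two screens
#'
#' Simulates re-running both monitoring campaigns with scaled sample sizes
#' and asks how often the comparison would declare a difference. Per
#' replicate, a true line-carrying frequency is drawn from each campaign's
#' posterior (its beta distribution), new screen counts are simulated as
#' `S* ~ Binomial(round(multiplier * n), p_true)`, the posteriors are
#' rebuilt from the simulated counts, and [prob_equal()] is evaluated. The
#' returned power is the proportion of replicates with `p < alpha`.
#'
#' @param post_a,post_b beta-convention [posterior_q()] objects.
#' @param n_multiplier_a,n_multiplier_b positive scale factors on each
#'   campaign's number of lines.
#' @param n_reps number of replicates (default 10000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return An object of class `replication_power` with fields `power`,
#'   `se` (binomial standard error), `n_reps`, `alpha`, `multipliers`,
#'   `seed` and the vector `p_values`.
#' @export
replication_power <- function(post_a, post_b, n_multiplier_a = 1,
                              n_multiplier_b = 1, n_reps = 10000L,
                              alpha = 0.05, seed = NULL) {
  check_posterior(post_a)
  check_posterior(post_b)
  if (post_a$method != "beta_approx" || post_b$method != "beta_approx") {
    stop_input("replication_power requires beta_approx posteriors")
  }
  if (!is.numeric(n_multiplier_a) || n_multiplier_a <= 0 ||
      !is.numeric(n_multiplier_b) || n_multiplier_b <= 0) {
    stop_input("multipliers must be positive")
  }
  n_reps <- assert_count(n_reps, "n_reps", min = 1L)
  assert_prob(alpha, "alpha")
  na_star <- max(1L, as.integer(round(n_multiplier_a * post_a$n)))
  nb_star <- max(1L, as.integer(round(n_multiplier_b * post_b$n)))
  p_values <- with_seed(seed, {
    pa_true <- rbeta(n_reps, post_a$shape1, post_a$shape2)
    pb_true <- rbeta(n_reps, post_b$shape1, post_b$shape2)
    sa <- rbinom(n_reps, na_star, pa_true)
    sb <- rbinom(n_reps, nb_star, pb_true)
    vapply(seq_len(n_reps), function(i) {
      prob_equal(posterior_q(sa[i], na_star, post_a$a),
                 posterior_q(sb[i], nb_star, post_b$a),
                 method = "quadrature")$p
    }, numeric(1))
  })
  power <- mean(p_values < alpha)
  structure(
    list(power = power,
         se = sqrt(power * (1 - power) / n_reps),
         n_reps = n_reps, alpha = alpha,
         multipliers = c(a = n_multiplier_a, b = n_multiplier_b),
         seed = seed, p_values = p_values),
    class = "replication_power"
  )
}

#' @export
print.replication_power <- function(x, ...) {
  cat(sprintf(
    "Replication power: %.3f +/- %.3f (n_reps = %d, alpha = %.2f, mult = %gx/%gx)\n",
    x$power, x$se, x$n_reps, x$alpha, x$multipliers["a"], x$multipliers["b"]))
  invisible(x)
}
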