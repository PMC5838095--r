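#' One generation of selection under the high-dose/refuge strategy
#'
#' One-locus, two-allele deterministic recursion. Larvae distribute between
#' Bt fields (proportion `phi`, the adoption rate) and refuges `(1 - phi)`;
#' genotype `G` survives with `W_G = phi * w_G_bt + (1 - phi) * w_G_ref`.
#' Survivors mate at random in a single pooled population, so genotypes
#' enter at Hardy-Weinberg proportions `(q^2, 2q(1-q), (1-q)^2)` and the
#' resistance allele frequency updates to
#' `q' = (q^2 W_RR + q(1-q) W_RS) / W_bar`.
#'
#' @param q current resistance allele frequency (vectorised).
#' @param phi proportion of the crop that is Bt in this generation.
#' @param bt_survival named survival triple `c(ss=, rs=, rr=)` on Bt maize.
#'   Under a high dose, `rs` and `ss` are near 0 and resistance is
#'   functionally recessive.
#' @param refuge_survival survival triple in the refuge (default all 1).
#' @return Updated frequency `q'`, same length as `q`.
#' @examples
#' step_generation(0.01, 0.5, c(ss = 0, rs = 0, rr = 1))  # 0.010099
#' @export
step_generation <- function(q, phi, bt_survival,
                            refuge_survival = c(ss = 1, rs = 1, rr = 1)) {
  assert_prob(q, "q")
  assert_prob(phi, "phi")
  bt_survival <- check_survival(bt_survival, "bt_survival")
  refuge_survival <- check_survival(refuge_survival, "refuge_survival")
  w <- phi * bt_survival + (1 - phi) * refuge_survival
  num <- q^2 * w[["rr"]] + q * (1 - q) * w[["rs"]]
  wbar <- q^2 * w[["rr"]] + 2 * q * (1 - q) * w[["rs"]] +
    (1 - q)^2 * w[["ss"]]
  if (any(wbar == 0)) {
    stop_numeric("population extinct: mean fitness is zero for some q")
  }
  pmin(pmax(num / wbar, 0), 1)
}

check_survival <- function(w, what) {
  if (is.null(names(w)) && length(w) == 3L) names(w) <- c("ss", "rs", "rr")
  if (!is.numeric(w) || length(w) != 3L ||
      !all(c("ss", "rs", "rr") %in% names(w))) {
    stop_input(what, " must be a numeric triple named ss, rs, rr")
  }
  assert_prob(unname(w), what)
  w[c("ss", "rs", "rr")]
}

#' Resistance-evolution scenario under time-varying Bt adoption
#'
#' Bundles the inputs of the forecasting model: the initial resistance
#' allele frequency (a point value, or a [posterior_q()] to draw from in
#' stochastic mode), the yearly Bt-adoption schedule, genotype survivals on
#' Bt and refuge plants, the number of pest generations per year, and the
#' frequency threshold taken to mean resistance has arrived.
#'
#' @param initial_q starting frequency in \[0, 1\], or a [posterior_q()].
#' @param adoption yearly adoption schedule: a data.frame with columns
#'   `year` and `proportion`, a named numeric vector (names are years), or
#'   a path to a two-column CSV `year,proportion`. Proportions are
#'   fractions, not percent; missing years take the last defined value
#'   (carried forward), and years before the first defined year take the
#'   first value.
#' @param generations_per_year pest generations per calendar year
#'   (default 2).
#' @param bt_survival genotype survival on Bt maize, default
#'   `c(ss = 0.01, rs = 0.02, rr = 1)` (high dose, functionally recessive).
#' @param refuge_survival genotype survival in the refuge, default all 1.
#' @param threshold_q frequency at which resistance is declared
#'   (default 0.5).
#' @param horizon_years number of years to simulate (default 100).
#' @param start_year first simulated year; defaults to the first year of
#'   the adoption schedule.
#' @param n_runs stochastic runs (default 10000; 300000 for a
#'   full-scale forecast).
#' @param population_size optional effective size for binomial allele
#'   resampling each generation; `NULL` keeps dynamics deterministic given
#'   the initial frequency.
#' @param seed RNG seed for stochastic mode.
#' @return An object of class `evolution_scenario`.
#' @export
evolution_scenario <- function(initial_q, adoption, generations_per_year = 2L,
                               bt_survival = c(ss = 0.01, rs = 0.02, rr = 1),
                               refuge_survival = c(ss = 1, rs = 1, rr = 1),
                               threshold_q = 0.5, horizon_years = 100L,
                               start_year = NULL, n_runs = 10000L,
                               population_size = NULL, seed = NULL) {
  if (!inherits(initial_q, "posterior_q")) assert_prob(initial_q, "initial_q")
  adoption <- read_adoption_schedule(adoption)
  generations_per_year <- assert_count(generations_per_year,
                                       "generations_per_year", min = 1L)
  assert_prob(threshold_q, "threshold_q")
  horizon_years <- assert_count(horizon_years, "horizon_years", min = 1L)
  n_runs <- assert_count(n_runs, "n_runs", min = 1L)
  if (!is.null(population_size)) {
    population_size <- assert_count(population_size, "population_size",
                                    min = 1L)
  }
  if (is.null(start_year)) start_year <- min(adoption$year)
  structure(
    list(initial_q = initial_q, adoption = adoption,
         generations_per_year = generations_per_year,
         bt_survival = check_survival(bt_survival, "bt_survival"),
         refuge_survival = check_survival(refuge_survival, "refuge_survival"),
         threshold_q = threshold_q, horizon_years = horizon_years,
         start_year = as.integer(start_year), n_runs = n_runs,
         population_size = population_size, seed = seed),
    class = "evolution_scenario"
  )
}

#' Read or normalise a yearly Bt-adoption schedule
#'
#' @param adoption a data.frame with columns `year` and `proportion`, a
#'   named numeric vector, or a CSV path.
#' @return A data.frame with integer `year` and numeric `proportion`,
#'   sorted by year.
#' @export
read_adoption_schedule <- function(adoption) {
  if (is.character(adoption) && length(adoption) == 1L) {
    adoption <- read.csv(adoption)
  }
  if (is.numeric(adoption) && !is.null(names(adoption))) {
    adoption <- data.frame(year = as.integer(names(adoption)),
                           proportion = as.numeric(adoption))
  }
  if (!is.data.frame(adoption) ||
      !all(c("year", "proportion") %in% names(adoption))) {
    stop_input("adoption schedule needs columns 'year' and 'proportion'")
  }
  if (nrow(adoption) == 0L) stop_input("adoption schedule is empty")
  assert_prob(adoption$proportion, "adoption proportion")
  adoption <- adoption[order(adoption$year), c("year", "proportion")]
  adoption$year <- as.integer(adoption$year)
  rownames(adoption) <- NULL
  adoption
}

# adoption proportion for each requested year, last value carried forward
phi_for_years <- function(adoption, years) {
  idx <- findInterval(years, adoption$year)
  idx[idx == 0L] <- 1L
  adoption$proportion[idx]
}

#' Deterministic years-to-resistance forecast
#'
#' Iterates [step_generation()] `generations_per_year` times per calendar
#' year over the adoption schedule, starting from a point initial
#' frequency, and reports the first year in which `q >= threshold_q`.
#'
#' @param scenario an [evolution_scenario()] with a numeric `initial_q` and
#'   no `population_size`.
#' @return An object of class `evolution_forecast`: `years` (years elapsed
#'   from the start year until the threshold, or `NA` if not reached within
#'   the horizon), `reached`, `final_q`, and `trajectory`, a data.frame with
#'   columns `year`, `generation` and `q` (generation 0 is the initial
#'   state).
#' @export
years_to_resistance <- function(scenario) {
  check_scenario(scenario, deterministic = TRUE)
  g <- scenario$generations_per_year
  years <- scenario$start_year + seq_len(scenario$horizon_years) - 1L
  phis <- phi_for_years(scenario$adoption, years)
  q <- scenario$initial_q
  n_gen <- scenario$horizon_years * g
  traj_year <- c(scenario$start_year, rep(years, each = g))
  traj_gen <- 0:n_gen
  traj_q <- c(q, rep(NA_real_, n_gen))
  reached_year <- if (q >= scenario$threshold_q) 0L else NA_integer_
  gen <- 0L
  if (is.na(reached_year)) {
    for (i in seq_along(years)) {
      for (j in seq_len(g)) {
        q <- step_generation(q, phis[i], scenario$bt_survival,
                             scenario$refuge_survival)
        gen <- gen + 1L
        traj_q[gen + 1L] <- q
      }
      if (q >= scenario$threshold_q) {
        reached_year <- i
        break
      }
    }
  }
  keep <- seq_len(gen + 1L)
  traj <- data.frame(year = traj_year[keep], generation = traj_gen[keep],
                     q = traj_q[keep])
  structure(
    list(years = reached_year, reached = !is.na(reached_year), final_q = q,
         threshold_q = scenario$threshold_q, trajectory = traj),
    class = "evolution_forecast"
  )
}

#' @export
print.evolution_forecast <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("Resistance (q >= %g) reached after %d year(s)\n",
                x$threshold_q, x$years))
  } else {
    cat(sprintf("Resistance not reached within horizon; final q = %.4g\n",
                x$final_q))
  }
  invisible(x)
}

#' Stochastic resistance-evolution forecast
#'
#' Runs the recursion `n_runs` times. The initial frequency is drawn from
#' the supplied posterior (or fixed at its mean when `init = "mean"`, the
#' second simulation mode); with a finite `population_size` N, allele
#' counts are resampled `Binomial(2N, q)/2N` after each generation.
#'
#' @param scenario an [evolution_scenario()].
#' @param init `"sample"` draws the initial frequency from the posterior;
#'   `"mean"` fixes it at the posterior mean. Ignored for a numeric
#'   `initial_q`.
#' @return An object of class `stochastic_forecast`: quantiles of the final
#'   frequency and of years-to-threshold, the fraction of runs reaching the
#'   threshold, `n_runs` and `seed`.
#' @export
run_stochastic <- function(scenario, init = c("sample", "mean")) {
  check_scenario(scenario, deterministic = FALSE)
  init <- match.arg(init)
  g <- scenario$generations_per_year
  years <- scenario$start_year + seq_len(scenario$horizon_years) - 1L
  phis <- phi_for_years(scenario$adoption, years)
  n <- scenario$n_runs
  pop <- scenario$population_size
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  with_seed(scenario$seed, {
    q <- if (inherits(scenario$initial_q, "posterior_q")) {
      if (init == "mean") rep(expected_q(scenario$initial_q), n)
      else posterior_sample(scenario$initial_q, n)
    } else {
      rep(scenario$initial_q, n)
    }
    initial_q <- q
    year_reached <- ifelse(q >= scenario$threshold_q, 0L, NA_integer_)
    for (i in seq_along(years)) {
      for (j in seq_len(g)) {
        q <- step_generation(q, phis[i], scenario$bt_survival,
                             scenario$refuge_survival)
        if (!is.null(pop)) q <- rbinom(n, 2L * pop, q) / (2 * pop)
      }
      hit <- is.na(year_reached) & q >= scenario$threshold_q
      year_reached[hit] <- i
    }
    structure(
      list(final_q_quantiles = quantile(q, probs, names = TRUE),
           mean_final_q = mean(q),
           mean_initial_q = mean(initial_q),
           fraction_reached = mean(!is.na(year_reached)),
           years_quantiles = if (any(!is.na(year_reached)))
             quantile(year_reached[!is.na(year_reached)], probs,
                      names = TRUE) else NULL,
           n_runs = n, init = init, seed = scenario$seed),
      class = "stochastic_forecast"
    )
  })
}

#' @export
print.stochastic_forecast <- function(x, ...) {
  cat(sprintf(
    "Stochastic forecast (%d runs, init = %s): %.1f%% reached threshold\n",
    x$n_runs, x$init, 100 * x$fraction_reached))
  cat("  final q quantiles:\n")
  print(round(x$final_q_quantiles, 6))
  invisible(x)
}

check_scenario <- function(scenario, deterministic) {
  if (!inherits(scenario, "evolution_scenario")) {
    stop_input("expected an evolution_scenario")
  }
  if (deterministic) {
    if (inherits(scenario$initial_q, "posterior_q")) {
      stop_input("years_to_resistance needs a point initial_q; ",
                 "use run_stochastic for a posterior")
    }
    if (!is.null(scenario$population_size)) {
      stop_input("years_to_resistance is deterministic; drop population_size")
    }
  }
  invisible(scenario)
}
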