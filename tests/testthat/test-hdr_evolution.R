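high_dose <- c(ss = 0, rs = 0, rr = 1)

test_that("one-generation recursion matches hand-evaluated and textbook forms", {
  # hand-evaluated: q = 0.01, phi = 0.5, recessive lethal heterozygote on Bt
  expect_equal(step_generation(0.01, 0.5, high_dose), 0.00505 / 0.50005,
               tolerance = 1e-9)
  # no Bt and a neutral refuge: no selection at all
  expect_equal(step_generation(0.123, 0, high_dose), 0.123)
  # fixation states are absorbing
  expect_equal(step_generation(0, 0.8, high_dose), 0)
  expect_equal(step_generation(1, 0.8, high_dose), 1)
  # with phi = 1 the recursion is the textbook one-locus selection formula
  for (q in c(0.01, 0.2, 0.7)) {
    w <- c(ss = 0.05, rs = 0.3, rr = 0.9)
    expect_equal(step_generation(q, 1, w), textbook_next_q(q, 0.9, 0.3, 0.05),
                 tolerance = 1e-12)
    # and for phi in (0,1) it matches the formula at the blended fitnesses
    phi <- 0.6
    expect_equal(step_generation(q, phi, w),
                 textbook_next_q(q, phi * 0.9 + (1 - phi),
                                 phi * 0.3 + (1 - phi),
                                 phi * 0.05 + (1 - phi)),
                 tolerance = 1e-12)
  }
  expect_error(step_generation(0.5, 1, c(ss = 0, rs = 0, rr = 0)),
               class = "f2screen_numeric_error")
})

test_that("trajectories stay in [0,1] and reproduce an independent re-evaluation", {
  adoption <- data.frame(year = c(2005, 2010, 2016),
                         proportion = c(0.35, 0.6, 0.74))
  scen <- evolution_scenario(0.0036, adoption,
                             bt_survival = c(ss = 0.01, rs = 0.02, rr = 1),
                             horizon_years = 60)
  fc <- years_to_resistance(scen)
  expect_true(all(fc$trajectory$q >= 0 & fc$trajectory$q <= 1))
  # step-by-step independent re-evaluation of the same recursion
  q <- 0.0036
  phi_of <- function(y) if (y < 2010) 0.35 else if (y < 2016) 0.6 else 0.74
  traj <- q
  for (year in 2005:2064) {
    for (g in 1:2) {
      w_rr <- phi_of(year) * 1 + (1 - phi_of(year))
      w_rs <- phi_of(year) * 0.02 + (1 - phi_of(year))
      w_ss <- phi_of(year) * 0.01 + (1 - phi_of(year))
      q <- textbook_next_q(q, w_rr, w_rs, w_ss)
      traj <- c(traj, q)
    }
    if (q >= 0.5) break
  }
  n <- min(length(traj), nrow(fc$trajectory))
  expect_equal(fc$trajectory$q[seq_len(n)], traj[seq_len(n)],
               tolerance = 1e-12)
  first_gen <- which(traj[-1] >= 0.5)[1]
  if (!is.na(first_gen)) {
    expect_equal(fc$years, as.integer(ceiling(first_gen / 2)))
  } else {
    expect_false(fc$reached)
  }
})

test_that("years to resistance respects thresholds, adoption and edge cases", {
  adoption <- data.frame(year = 2016, proportion = 0.74)
  # threshold at or below the initial frequency: resistance at year 0
  scen0 <- evolution_scenario(0.6, adoption, threshold_q = 0.5,
                              horizon_years = 10)
  expect_equal(years_to_resistance(scen0)$years, 0L)
  # no Bt anywhere: frequency never moves
  scen_null <- evolution_scenario(0.0036,
                                  data.frame(year = 2016, proportion = 0),
                                  horizon_years = 20)
  fc_null <- years_to_resistance(scen_null)
  expect_false(fc_null$reached)
  expect_equal(unique(fc_null$trajectory$q), 0.0036)
  # monotone: more Bt, no later resistance
  yrs <- vapply(c(0.3, 0.6, 0.9), function(phi) {
    scen <- evolution_scenario(0.0036, data.frame(year = 1, proportion = phi),
                               horizon_years = 400)
    years_to_resistance(scen)$years
  }, integer(1))
  expect_true(all(diff(yrs) <= 0))
  # monotone: fitter heterozygotes on Bt, no later resistance (w_rs >= w_ss
  # keeps R advantageous when rare, so the threshold is reached)
  yrs_h <- vapply(c(0.02, 0.1, 0.3), function(w_rs) {
    scen <- evolution_scenario(
      0.0036, adoption, horizon_years = 2000,
      bt_survival = c(ss = 0.01, rs = w_rs, rr = 1))
    years_to_resistance(scen)$years
  }, integer(1))
  expect_true(all(!is.na(yrs_h)))
  expect_true(all(diff(yrs_h) <= 0))
  # monotone: higher threshold, no earlier resistance
  yrs_t <- vapply(c(0.1, 0.5, 0.9), function(th) {
    scen <- evolution_scenario(0.0036, adoption, threshold_q = th,
                               horizon_years = 400)
    years_to_resistance(scen)$years
  }, integer(1))
  expect_true(all(diff(yrs_t) >= 0))
})

test_that("adoption schedules carry the last value forward", {
  sched <- read_adoption_schedule(
    data.frame(year = c(2016, 2005), proportion = c(0.74, 0.35)))
  expect_equal(sched$year, c(2005L, 2016L))  # sorted
  path <- system.file("extdata", "bt_adoption_ebro.csv", package = "f2screen")
  from_csv <- read_adoption_schedule(path)
  expect_equal(from_csv, sched)
  scen <- evolution_scenario(0.01, sched, horizon_years = 20)
  fc <- years_to_resistance(scen)
  # years 2005..2015 use 0.35; 2016 onward use 0.74 (carried forward)
  expect_equal(min(fc$trajectory$year), 2005)
  expect_error(read_adoption_schedule(data.frame(year = 1, prop = 0.3)),
               class = "f2screen_input_error")
})

test_that("stochastic forecasts are seeded, consistent and collapse correctly", {
  adoption <- data.frame(year = 2016, proportion = 0.74)
  # degenerate initialisation, no drift: every run equals the deterministic
  # path (horizon short of the threshold, where both simulators still evolve)
  scen_pt <- evolution_scenario(0.0036, adoption, horizon_years = 10,
                                n_runs = 50, seed = 5)
  st <- run_stochastic(scen_pt)
  det <- years_to_resistance(
    evolution_scenario(0.0036, adoption, horizon_years = 10))
  expect_false(det$reached)
  expect_equal(unname(st$final_q_quantiles["2.5%"]),
               unname(st$final_q_quantiles["97.5%"]))
  expect_equal(unname(st$final_q_quantiles["50%"]), det$final_q,
               tolerance = 1e-12)
  # posterior initialisation: mean initial q matches E(q) within 3 s.e.
  post <- posterior_q(1, 137)
  scen_post <- evolution_scenario(post, adoption, horizon_years = 1,
                                  n_runs = 1e5, seed = 6)
  st_post <- run_stochastic(scen_post, init = "sample")
  sd_q <- sqrt(post$shape1 * post$shape2 /
                 ((post$shape1 + post$shape2)^2 *
                    (post$shape1 + post$shape2 + 1))) / 4
  expect_lt(abs(st_post$mean_initial_q - expected_q(post)),
            3 * sd_q / sqrt(1e5))
  # init = "mean" pins every run at the posterior mean
  st_mean <- run_stochastic(scen_post, init = "mean")
  expect_equal(st_mean$mean_initial_q, expected_q(post), tolerance = 1e-12)
  # determinism contract
  st2 <- run_stochastic(scen_post, init = "sample")
  expect_identical(st_post$final_q_quantiles, st2$final_q_quantiles)
  # finite-population runs remain valid frequencies
  scen_fin <- evolution_scenario(0.05, adoption, horizon_years = 15,
                                 n_runs = 200, population_size = 500,
                                 seed = 8)
  st_fin <- run_stochastic(scen_fin)
  expect_true(all(st_fin$final_q_quantiles >= 0 &
                    st_fin$final_q_quantiles <= 1))
})
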