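# Independent oracles used across the suite. These simulate or enumerate the
# generative stories forward and never call the closed forms they check.

# Monte-Carlo oracle for the per-line miss probability: one heterozygous
# founding parent, F1 carriers Bernoulli(1/2), one uniformly drawn mate per
# female, RR neonates Binomial(k_i, 1/4 * (1 - mu) * carrier x carrier).
mc_p_no <- function(n_f, n_m, k, mu, reps, chunk = 1e5L) {
  if (length(k) == 1L) k <- rep(k, n_f)
  missed <- 0L
  done <- 0L
  while (done < reps) {
    nn <- min(chunk, reps - done)
    m <- rbinom(nn, n_m, 0.5)                       # carrier males per line
    fem <- matrix(rbinom(nn * n_f, 1L, 0.5), nn)    # carrier females
    detected <- rep(FALSE, nn)
    for (i in seq_len(n_f)) {
      mate_carrier <- rbinom(nn, 1L, m / n_m)
      p <- fem[, i] * mate_carrier * 0.25 * (1 - mu)
      detected <- detected | rbinom(nn, k[i], p) > 0L
    }
    missed <- missed + sum(!detected)
    done <- done + nn
  }
  missed / reps
}

# Exact enumeration of the F2 homozygous-resistant fraction: iterate over all
# parental gamete transmissions to build the exact F1 genotype distribution,
# then over all F1 x F1 gamete transmissions under random sib-mating.
enumerate_rr_fraction <- function(g_mother, g_father) {
  # transmission distribution of one parent with g R alleles (out of 2)
  transmit <- function(g) c(`0` = 1 - g / 2, `1` = g / 2)
  f1 <- outer(transmit(g_mother), transmit(g_father))  # P(F1 genotype = i+j)
  geno_probs <- c(`0` = 0, `1` = 0, `2` = 0)
  for (i in 0:1) for (j in 0:1) {
    geno_probs[[as.character(i + j)]] <-
      geno_probs[[as.character(i + j)]] + f1[i + 1, j + 1]
  }
  # random F1 x F1 mating: P(RR offspring) = E[g/2]^2 by independence of the
  # two parents, but enumerate fully rather than rely on that identity
  rr <- 0
  for (gm in 0:2) for (gf in 0:2) {
    rr <- rr + geno_probs[[as.character(gm)]] * geno_probs[[as.character(gf)]] *
      (gm / 2) * (gf / 2)
  }
  rr
}

# Textbook one-locus selection recursion for constant genotype fitnesses,
# written independently of step_generation.
textbook_next_q <- function(q, w_rr, w_rs, w_ss) {
  wbar <- q^2 * w_rr + 2 * q * (1 - q) * w_rs + (1 - q)^2 * w_ss
  (q^2 * w_rr + q * (1 - q) * w_rs) / wbar
}

make_lines <- function(n, n_f = 27, n_m = 27, k = 11, mu = 0.132) {
  lapply(seq_len(n), function(i) {
    line_record(sprintf("L%03d", i), n_f, n_m, k, mu)
  })
}
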