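#' Default F1 family-size model for the synthetic screen
#'
#' Study-condition defaults for the generator: mean F1 cage composition of
#' 27.4 females and 27.2 males and 11.4 screened neonates per F1 female,
#' with dispersions back-calculated from the reported standard errors over
#' 137 lines (s.e.m. 1.0, 1.0 and 0.6 -> sd about 11.7, 11.7 and 7.0).
#' Counts are drawn from negative-binomial distributions matched to these
#' means and sds (Poisson when the sd is at or below the Poisson floor),
#' truncated at 1 adult per sex and at 0 neonates.
#'
#' @param mean_females,sd_females F1 females per cage.
#' @param mean_males,sd_males F1 males per cage.
#' @param mean_neonates,sd_neonates screened F2 neonates per F1 female.
#' @return A list of class `family_model`.
#' @export
family_model <- function(mean_females = 27.4, sd_females = 11.7,
                         mean_males = 27.2, sd_males = 11.7,
                         mean_neonates = 11.4, sd_neonates = 7.0) {
  vals <- c(mean_females, sd_females, mean_males, sd_males,
            mean_neonates, sd_neonates)
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0)) {
    stop_input("family model parameters must be non-negative numbers")
  }
  structure(list(mean_females = mean_females, sd_females = sd_females,
                 mean_males = mean_males, sd_males = sd_males,
                 mean_neonates = mean_neonates, sd_neonates = sd_neonates),
            class = "family_model")
}

# negative-binomial (or Poisson) count draws matched to mean/sd, floored
draw_counts <- function(n, mean, sd, min_value) {
  x <- if (sd^2 > mean && mean > 0) {
    size <- mean^2 / (sd^2 - mean)
    rnbinom(n, size = size, mu = mean)
  } else {
    rpois(n, mean)
  }
  pmax(x, min_value)
}

#' Simulate a full F2 screen with known ground truth
#'
#' Forward model of the four-step screen. Per line: the four parental
#' gametic haplotypes are i.i.d. Bernoulli draws at the true allele
#' frequency; a line with at least one R allele is a carrier. R is
#' propagated exactly through the F1 (each offspring inherits R from a
#' parent of genotype `g` with probability `g/2`, covering both-het and
#' homozygous founders), each F1 female's brood is sired by one male drawn
#' uniformly with replacement from the line's males, and each screened
#' neonate is a surviving homozygous-resistant with probability
#' `(g_f/2)(g_m/2)(1 - mu)`. A line is recorded positive when at least one
#' surviving RR neonate appears — twice in independent generations when
#' `rescreen = TRUE`, emulating the F3 confirmation screen (there is no
#' false-positive mechanism in the model, so rescreening can only remove
#' true carriers that fail the second draw).
#'
#' @param q_true true resistance allele frequency.
#' @param n_lines number of isofemale lines screened.
#' @param family single [family_model()] controlling cage compositions and
#'   neonate counts.
#' @param mu screen-independent control mortality (default 0.132).
#' @param a gametic haplotypes per line (default 4).
#' @param rescreen require a second independent positive screen
#'   (default `FALSE`).
#' @param seed RNG seed; all randomness flows from it.
#' @return An object of class `screen_sim`: `screen` (a [screen_count()]),
#'   `lines` (list of [line_record()]), and `truth`, a data.frame with
#'   columns `line_id`, `n_r_alleles`, `carrier` and `positive`.
#' @examples
#' sim <- simulate_screen(0.005, 137, seed = 1)
#' sim$screen
#' @export
simulate_screen <- function(q_true, n_lines, family = family_model(),
                            mu = 0.132, a = 4L, rescreen = FALSE,
                            seed = NULL) {
  assert_prob(q_true, "q_true")
  n_lines <- assert_count(n_lines, "n_lines", min = 1L)
  if (!inherits(family, "family_model")) {
    stop_input("family must be a family_model")
  }
  assert_prob(mu, "mu")
  a <- assert_count(a, "a", min = 2L)
  if (a %% 2L != 0L) stop_input("a must be even (two alleles per parent)")
  with_seed(seed, {
    # parental allele counts: a/2 haplotypes per parent
    g_mother <- rbinom(n_lines, a %/% 2L, q_true)
    g_father <- rbinom(n_lines, a %/% 2L, q_true)
    n_f <- draw_counts(n_lines, family$mean_females, family$sd_females, 1L)
    n_m <- draw_counts(n_lines, family$mean_males, family$sd_males, 1L)
    n_r <- g_mother + g_father
    carrier <- n_r > 0L
    positive <- logical(n_lines)
    lines <- vector("list", n_lines)
    line_ids <- sprintf("L%03d", seq_len(n_lines))
    for (i in seq_len(n_lines)) {
      k <- draw_counts(n_f[i], family$mean_neonates, family$sd_neonates, 0L)
      lines[[i]] <- line_record(line_ids[i], n_f[i], n_m[i], k, mu)
      if (!carrier[i]) next
      det <- screen_line_once(g_mother[i], g_father[i], n_f[i], n_m[i], k, mu)
      if (det && rescreen) {
        k2 <- draw_counts(n_f[i], family$mean_neonates, family$sd_neonates, 0L)
        det <- screen_line_once(g_mother[i], g_father[i], n_f[i], n_m[i],
                                k2, mu)
      }
      positive[i] <- det
    }
    truth <- data.frame(line_id = line_ids, n_r_alleles = n_r,
                        carrier = carrier, positive = positive)
    structure(
      list(screen = screen_count(n_lines, sum(positive)), lines = lines,
           truth = truth, q_true = q_true, mu = mu, a = a,
           rescreen = rescreen, seed = seed),
      class = "screen_sim"
    )
  })
}

# one screening pass over a carrier line; exact Mendelian transmission
screen_line_once <- function(g_mother, g_father, n_f, n_m, k, mu) {
  g_fem <- rbinom(n_f, 1L, g_mother / 2) + rbinom(n_f, 1L, g_father / 2)
  g_mal <- rbinom(n_m, 1L, g_mother / 2) + rbinom(n_m, 1L, g_father / 2)
  mate <- sample.int(n_m, n_f, replace = TRUE)
  p_rr_surv <- (g_fem / 2) * (g_mal[mate] / 2) * (1 - mu)
  any(rbinom(n_f, k, p_rr_surv) > 0L)
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic F2 screen: q_true = %g, %d lines -> %d carriers, %d positive\n",
    x$q_true, x$screen$n_lines, sum(x$truth$carrier), x$screen$n_positive))
  invisible(x)
}

#' Write a simulated screen as a line-table CSV
#'
#' Serialises the per-line records of a [simulate_screen()] result in the
#' schema read by [read_line_table()] (per-female neonate counts joined
#' with semicolons). Writing, reading and re-writing the table is
#' byte-identical.
#'
#' @param sim a `screen_sim` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
generate_line_table <- function(sim, path) {
  if (!inherits(sim, "screen_sim")) stop_input("sim must be a screen_sim")
  write_line_table(sim$lines, path)
}

#' Render a synthetic egg-mass photograph
#'
#' Draws `n_eggs` non-overlapping elliptical egg blobs at a fixed blue
#' intensity on a white background, recording the exact egg count and the
#' exact number of egg pixels — the ground truth for the imaging pipeline.
#' Egg pixels get bright red/green values so the blue channel alone is
#' informative. Optional Gaussian noise perturbs all channels after the
#' truth is recorded.
#'
#' @param n_eggs number of eggs to place (>= 0).
#' @param width,height canvas size in pixels.
#' @param egg_area_mean,egg_area_sd target blob areas in pixels.
#' @param blue_intensity blue value of egg pixels (default 50, inside the
#'   default calibration window).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (default 0, noiseless).
#' @param seed RNG seed.
#' @param max_tries placement attempts per egg before giving up.
#' @return A list of class `egg_image_sim`: `image` (height x width x 3
#'   integer array, 0..255), `n_eggs`, `egg_pixels` (noiseless truth).
#' @export
generate_egg_image <- function(n_eggs, width = 200L, height = 200L,
                               egg_area_mean = 60, egg_area_sd = 10,
                               blue_intensity = 50L, noise_sd = 0,
                               seed = NULL, max_tries = 1000L) {
  n_eggs <- assert_count(n_eggs, "n_eggs")
  width <- assert_count(width, "width", min = 8L)
  height <- assert_count(height, "height", min = 8L)
  blue_intensity <- assert_count(blue_intensity, "blue_intensity")
  if (blue_intensity > 255L) stop_input("blue_intensity must be <= 255")
  with_seed(seed, {
    egg_mask <- matrix(FALSE, nrow = height, ncol = width)
    placed <- 0L
    while (placed < n_eggs) {
      area <- max(8, rnorm(1, egg_area_mean, egg_area_sd))
      aspect <- runif(1, 0.6, 1)
      semi_b <- sqrt(area / (pi * aspect))   # semi-axes: a = aspect * b
      semi_a <- aspect * semi_b
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- runif(1, semi_b + 1, width - semi_b - 1)
        cy <- runif(1, semi_b + 1, height - semi_b - 1)
        theta <- runif(1, 0, pi)
        xr <- ceiling(semi_b) + 1L
        xs <- max(1L, floor(cx - xr)):min(width, ceiling(cx + xr))
        ys <- max(1L, floor(cy - xr)):min(height, ceiling(cy + xr))
        dx <- outer(rep(1, length(ys)), xs - cx)
        dy <- outer(ys - cy, rep(1, length(xs)))
        u <- dx * cos(theta) + dy * sin(theta)
        v <- -dx * sin(theta) + dy * cos(theta)
        inside <- (u / semi_a)^2 + (v / semi_b)^2 <= 1
        if (!any(inside)) next
        sub <- egg_mask[ys, xs, drop = FALSE]
        if (any(sub & inside)) next     # overlap: reject and retry
        sub[inside] <- TRUE
        egg_mask[ys, xs] <- sub
        ok <- TRUE
        break
      }
      if (!ok) {
        stop_input("canvas too small to place ", n_eggs,
                   " non-overlapping eggs (placed ", placed, ")")
      }
      placed <- placed + 1L
    }
    img <- array(255L, dim = c(height, width, 3L))
    red <- matrix(255L, height, width)
    green <- matrix(255L, height, width)
    blue <- matrix(255L, height, width)
    red[egg_mask] <- 235L
    green[egg_mask] <- 225L
    blue[egg_mask] <- blue_intensity
    img[, , 1L] <- red
    img[, , 2L] <- green
    img[, , 3L] <- blue
    truth_pixels <- sum(egg_mask)
    if (noise_sd > 0) {
      img <- img + array(round(rnorm(length(img), 0, noise_sd)), dim = dim(img))
      img[img < 0L] <- 0L
      img[img > 255L] <- 255L
    }
    storage.mode(img) <- "integer"
    structure(list(image = img, n_eggs = n_eggs, egg_pixels = truth_pixels,
                   blue_intensity = blue_intensity, noise_sd = noise_sd,
                   seed = seed),
              class = "egg_image_sim")
  })
}

#' @export
print.egg_image_sim <- function(x, ...) {
  cat(sprintf("Synthetic egg image: %d eggs, %d egg pixels, %dx%d px\n",
              x$n_eggs, x$egg_pixels, dim(x$image)[2L], dim(x$image)[1L]))
  invisible(x)
}
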