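#' Per-line F1 family structure of an isofemale line
#'
#' Holds the quantities that drive the line's detection probability: the
#' numbers of F1 females and males placed in the sib-mating cage, the number
#' of F2 neonates screened per F1 female, and the screen-independent control
#' mortality `mu` measured on conventional maize.
#'
#' @param line_id line identifier.
#' @param n_f1_females,n_f1_males F1 adults in the mating cage, integers
#'   `>= 1`.
#' @param neonates_per_female screened F2 neonates per F1 female: either a
#'   vector of length `n_f1_females` or a single (possibly non-integer mean)
#'   count broadcast to all females. Non-negative.
#' @param control_mortality screen-independent neonate mortality `mu` in
#'   \[0, 1\].
#' @param region optional sampling-region label.
#' @return An object of class `line_record`.
#' @examples
#' line_record("P350", 27, 27, 11, 0.132)
#' @export
line_record <- function(line_id, n_f1_females, n_f1_males,
                        neonates_per_female, control_mortality,
                        region = NA_character_) {
  n_f1_females <- assert_count(n_f1_females, "n_f1_females", min = 1L)
  n_f1_males <- assert_count(n_f1_males, "n_f1_males", min = 1L)
  if (!is.numeric(neonates_per_female) || anyNA(neonates_per_female) ||
      any(neonates_per_female < 0)) {
    stop_input("neonates_per_female must be non-negative")
  }
  if (length(neonates_per_female) == 1L) {
    neonates_per_female <- rep(neonates_per_female, n_f1_females)
  }
  if (length(neonates_per_female) != n_f1_females) {
    stop_input("neonates_per_female must have length 1 or n_f1_females (",
               n_f1_females, "), got ", length(neonates_per_female))
  }
  assert_prob(control_mortality, "control_mortality (mu)")
  structure(
    list(line_id = as.character(line_id), region = as.character(region),
         n_f1_females = n_f1_females, n_f1_males = n_f1_males,
         neonates_per_female = as.numeric(neonates_per_female),
         control_mortality = control_mortality),
    class = "line_record"
  )
}

#' @export
print.line_record <- function(x, ...) {
  cat(sprintf(
    "Line %s: %d F1 females x %d males, %.1f neonates/female (mu = %.3f)\n",
    x$line_id, x$n_f1_females, x$n_f1_males, mean(x$neonates_per_female),
    x$control_mortality))
  invisible(x)
}

#' Probability of missing a resistance allele present in a line (P_No)
#'
#' Type-II error of the screen for a single isofemale line, under the
#' mass-sib-mating model: one founding parent is heterozygous, so each F1
#' adult carries R independently with probability 1/2; each F1 female's
#' brood is sired by a single male drawn uniformly (with replacement across
#' females) from the line's `n_m` males; an F2 neonate of a carrier x
#' carrier cross is homozygous resistant with probability 1/4 and is scored
#' only if it survives the screen-independent control mortality `mu`. A line
#' is detected when at least one surviving RR neonate appears.
#'
#' Conditioning on the number `m` of carrier males gives the closed form
#' \deqn{P_{No} = \sum_{m=0}^{n_m} \binom{n_m}{m} 2^{-n_m}
#'   \prod_i \left[1 - \tfrac{1}{2}\tfrac{m}{n_m}(1 - \beta^{k_i})\right],
#'   \qquad \beta = 1 - \tfrac{1-\mu}{4},}
#' where \eqn{k_i} is the number of neonates screened from female \eqn{i}.
#'
#' @param line a [line_record()] (or a list of them, returning a vector).
#' @return `P_No` in \[0, 1\].
#' @examples
#' p_no(line_record("L1", 1, 1, 1, 0))   # 15/16
#' @export
p_no <- function(line) {
  if (is.list(line) && !inherits(line, "line_record")) {
    return(vapply(line, p_no, numeric(1)))
  }
  if (!inherits(line, "line_record")) {
    stop_input("expected a line_record")
  }
  p_no_core(line$n_f1_females, line$n_f1_males, line$neonates_per_female,
            line$control_mortality)
}

p_no_core <- function(n_f, n_m, k, mu) {
  beta <- 1 - (1 - mu) / 4
  m <- 0:n_m
  w <- dbinom(m, n_m, 0.5)
  # rows: carrier-male count m; cols: F1 females
  per_female_miss <- 1 - 0.5 * outer(m / n_m, 1 - beta^k)
  sum(w * exp(rowSums(log(per_female_miss))))
}

#' Detection summary across the screened lines
#'
#' Per-line detection probabilities `1 - P_No`, their mean (the
#' experiment-wise detection probability), and the fraction of lines
#' strictly above / strictly below each threshold, plus the empirical
#' cumulative distribution of detection for plotting.
#'
#' @param lines a list of [line_record()] objects.
#' @param thresholds detection-probability thresholds; default
#'   `c(0.80, 0.95)`.
#' @return An object of class `detection_summary` with fields `per_line`
#'   (named vector), `experiment_wise`, `fraction_above`, `fraction_below`
#'   and `cdf` (a data.frame of sorted detection values and cumulative
#'   probability).
#' @export
detection_summary <- function(lines, thresholds = c(0.80, 0.95)) {
  if (inherits(lines, "line_record")) lines <- list(lines)
  if (!is.list(lines) || length(lines) == 0L) {
    stop_input("lines must be a non-empty list of line_record objects")
  }
  assert_prob(thresholds, "thresholds")
  det <- 1 - p_no(lines)
  names(det) <- vapply(lines, function(l) l$line_id, character(1))
  srt <- sort(det)
  structure(
    list(per_line = det,
         experiment_wise = mean(det),
         fraction_above = setNames(
           vapply(thresholds, function(t) mean(det > t), numeric(1)),
           format(thresholds)),
         fraction_below = setNames(
           vapply(thresholds, function(t) mean(det < t), numeric(1)),
           format(thresholds)),
         cdf = data.frame(detection = srt,
                          cumulative = seq_along(srt) / length(srt))),
    class = "detection_summary"
  )
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf("Experiment-wise detection probability: %.1f%% (%d lines)\n",
              100 * x$experiment_wise, length(x$per_line)))
  for (i in seq_along(x$fraction_above)) {
    cat(sprintf("  lines with detection > %s: %.1f%%; < %s: %.1f%%\n",
                names(x$fraction_above)[i], 100 * x$fraction_above[i],
                names(x$fraction_below)[i], 100 * x$fraction_below[i]))
  }
  invisible(x)
}
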