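#' Aggregate outcome of an F2 screen
#'
#' The sufficient statistic of the screen: `n_lines` isofemale lines were
#' carried through the F2 screen and `n_positive` of them were confirmed
#' (true-positive) resistance carriers.
#'
#' @param n_lines number of lines screened (N), a positive integer.
#' @param n_positive number of true-positive lines (S), `0 <= S <= N`.
#' @return An object of class `screen_count` with fields `n_lines` and
#'   `n_positive`.
#' @examples
#' screen_count(137, 1)
#' @export
screen_count <- function(n_lines, n_positive) {
  n_lines <- assert_count(n_lines, "n_lines", min = 1L)
  n_positive <- assert_count(n_positive, "n_positive", min = 0L)
  if (n_positive > n_lines) stop_input("n_positive (S) cannot exceed n_lines (N)")
  structure(list(n_lines = n_lines, n_positive = n_positive),
            class = "screen_count")
}

#' @export
print.screen_count <- function(x, ...) {
  cat("F2 screen counts: S =", x$n_positive, "positive of N =", x$n_lines,
      "lines\n")
  invisible(x)
}

#' Probability that an isofemale line carries a resistance allele
#'
#' Each line is founded by a single mated pair and therefore samples `a`
#' gametic haplotypes (four for two diploid parents) from the population.
#' Under panmixia the haplotypes are independent draws at allele frequency
#' `q`, so the line carries at least one resistance allele with probability
#' `1 - (1 - q)^a`.
#'
#' @param q resistance allele frequency, in \[0, 1\] (vectorised).
#' @param a number of gametic haplotypes sampled per line, integer `>= 1`
#'   (default 4).
#' @return Carrier probability, same length as `q`.
#' @examples
#' line_carrier_prob(0.0036)        # ~ 0.0143
#' @export
line_carrier_prob <- function(q, a = 4L) {
  assert_prob(q, "q")
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 1) {
    stop_input("a (alleles per line) must be a number >= 1")
  }
  1 - (1 - q)^a
}

#' Expected homozygous-resistant fraction among F2 offspring
#'
#' Exact Mendelian expectation for the F2 of an isofemale line under random
#' sib-mating of the F1. With a single heterozygous founding parent, half the
#' F1 carry R, the F1 allele frequency is 1/4, and random mating yields
#' `(1/4)^2 = 1/16` homozygous-resistant F2. With both parents heterozygous
#' the F1 allele frequency is 1/2 and the RR fraction is 1/4. A line with no
#' R allele yields none.
#'
#' @param parental_config one of `"single-het-parent"`, `"both-het-parents"`,
#'   `"no-R"`.
#' @return The exact RR fraction (1/16, 1/4 or 0).
#' @examples
#' expected_rr_fraction_f2("single-het-parent")  # 0.0625
#' @export
expected_rr_fraction_f2 <- function(parental_config = c("single-het-parent",
                                                        "both-het-parents",
                                                        "no-R")) {
  if (!is.character(parental_config) || length(parental_config) < 1L ||
      !all(parental_config[1L] %in% c("single-het-parent",
                                      "both-het-parents", "no-R"))) {
    stop_input("unknown parental configuration: ",
               paste(parental_config[1L], collapse = ", "))
  }
  parental_config <- match.arg(parental_config)
  # exact rationals; 1/16 and 1/4 are exact in binary floating point
  switch(parental_config,
         "single-het-parent" = 1 / 16,
         "both-het-parents"  = 1 / 4,
         "no-R"              = 0)
}
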