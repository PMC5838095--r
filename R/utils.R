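# internal validation / RNG helpers

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("f2screen_input_error", "error")))
}

stop_state <- function(...) {
  stop(errorCondition(paste0(...), class = c("f2screen_state_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("f2screen_numeric_error", "error")))
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_input(what, " must be a probability in [0, 1]")
  }
  invisible(x)
}

assert_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x != round(x))) {
    stop_input(what, " must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

# Evaluate `code` under set.seed(seed) without clobbering the caller's RNG
# stream; seed = NULL leaves the stream untouched (and advancing).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_input("seed must be a single integer or NULL")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}
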