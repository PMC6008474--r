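#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats coef glm glm.fit glm.control lm pchisq pnorm qnorm rbinom
#'   rnorm runif sd var vcov complete.cases setNames plogis as.formula anova
#' @importFrom utils head
NULL

# error helper carrying a subclass so callers can distinguish failure modes
stop_repromr <- function(msg, class) {
  abort(msg, class = c(class, "repromr_error"))
}

assert_that <- function(ok, msg, class = "repromr_invalid_argument") {
  if (!isTRUE(ok)) stop_repromr(msg, class)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x, lo = 0, hi = 1, open = TRUE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
}

# Derive a child RNG seed from a base seed without touching global RNG state.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483587) + 1L
}

# Run `expr` under a local RNG stream seeded with `seed`; restores (or clears)
# the caller's .Random.seed so no global state leaks.
with_seed <- function(seed, expr) {
  assert_that(is_count(seed) || (is.numeric(seed) && seed == floor(seed)),
              "`seed` must be a single integer")
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483587))
  expr
}

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & a1 %in% names(DNA_COMPLEMENT) &
    unname(DNA_COMPLEMENT[a1]) == a2
}
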