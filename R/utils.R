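# Internal helpers shared across modules: typed errors, deterministic
# sub-stream seeding, and percentile conventions.

stop_input <- function(msg, class = "ampcontext_input_error", ...) {
  rlang::abort(msg, class = c(class, "ampcontext_error"), ...)
}

stop_config <- function(msg, ...) {
  stop_input(msg, class = "ampcontext_config_error", ...)
}

stop_format <- function(msg, ...) {
  stop_input(msg, class = "ampcontext_format_error", ...)
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_config(sprintf("`%s` must be a probability in [0, 1].", what))
  }
  invisible(x)
}

check_count <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop_config(sprintf("`%s` must be a nonnegative integer.", what))
  }
  invisible(x)
}

#' Deterministic sub-stream seed from a label
#'
#' Derives a reproducible child seed from a base seed and a character label
#' (sample id, section id, gene name, ...) by a stable polynomial string
#' hash.  Used so that per-unit random streams do not depend on iteration
#' order and adding a unit leaves earlier units untouched.
#'
#' @param seed Integer base seed.
#' @param label Character scalar identifying the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, label) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Percentile with linear interpolation (R's default type-7 convention);
# isolated here so the stratification and spatial modules share one rule.
percentile <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

# Two-decimal presentation rounding. R's round() implements IEEE
# round-half-to-even, which reproduces every printed cohort rate.
round2 <- function(x) round(x, 2)
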