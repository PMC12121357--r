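#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats rpois rmultinom rlnorm runif rbinom
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# typed error helpers: every user-facing validation failure carries a class so
# callers (and tests) can distinguish bad input from bad configuration
stop_input <- function(msg, ...) {
  abort(msg, class = "asvbiogeo_input_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "asvbiogeo_config_error", ...)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop_input(sprintf(
      "%s must be nonempty uppercase A/C/G/T; %d offending entr%s (first: '%s')",
      what, sum(bad), if (sum(bad) == 1L) "y" else "ies",
      substr(x[which(bad)[1L]], 1L, 40L)
    ))
  }
  invisible(x)
}
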