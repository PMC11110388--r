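#' @importFrom rlang abort warn %||% .data
#' @importFrom stats median quantile rnorm runif rbeta rbinom qnorm plogis qlogis uniroot setNames
#' @importFrom utils head
NULL

#' Round half away from zero at a fixed number of decimals
#'
#' Base [round()] rounds half to even ("banker's rounding"); published
#' diagnostic-accuracy tables conventionally round half up, so 6.125 prints
#' as 6.13. Full precision should be retained internally and this applied
#' only at presentation time.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(6.125, 2) # 6.13, where round(6.125, 2) gives 6.12
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# stage-level child seeds derived from one master seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(cohort = 11L, subcohort = 23L, linkage = 37L, fuzz = 53L)
  off <- if (is.character(stage)) offsets[[stage]] else as.integer(stage)
  as.integer((abs(seed) * 7919 + off * 104729) %% 2147483629)
}

# configuration-error helper naming the offending field
config_abort <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "triagecc_config_error")
}

assert_prob <- function(x, field, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) config_abort(field, if (open) "must lie strictly in (0, 1)"
                        else "must lie in [0, 1]")
  invisible(x)
}

assert_weights <- function(x, field) {
  assert_prob(x, field)
  if (abs(sum(x) - 1) > 1e-9)
    config_abort(field, sprintf("weights must sum to 1 (got %.12f)", sum(x)))
  invisible(x)
}
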