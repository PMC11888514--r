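# internal helpers shared across modules

# round half away from zero, matching how the trial tables display percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# percentage of num/den, NA (not 0) when the denominator is empty
pct_of <- function(num, den, digits = 0) {
  if (is.na(den) || den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_field(field, "must be a single finite probability in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)) || (strict && any(x <= 0)) ||
      (!strict && any(x < 0)))
    stop_field(field, if (strict) "must be finite and > 0" else "must be finite and >= 0")
  invisible(x)
}

# deterministic per-stage seed derived from a master seed; keeps each generated
# sub-table reproducible on its own while using base R's single RNG stream
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + match(
    stage, c("participants", "urine", "selfreports", "events", "calibration")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
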