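# internal validation helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_sprcoat <- function(..., class) {
  stop(structure(
    class = c(class, "sprcoat_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_sprcoat(name, " must be a single finite number",
                 class = "sprcoat_validation_error")
  }
  ok_lower <- if (allow_zero_lower) x >= lower else x > lower
  if (!ok_lower || x > upper) {
    bound <- if (allow_zero_lower) ">= " else "> "
    stop_sprcoat(name, " must be ", bound, lower,
                 if (is.finite(upper)) paste0(" and <= ", upper),
                 " (got ", format(x), ")",
                 class = "sprcoat_validation_error")
  }
  x
}

check_flag <- function(cond, ...) {
  if (!isTRUE(cond)) stop_sprcoat(..., class = "sprcoat_validation_error")
  invisible(TRUE)
}

# half-away-from-zero rounding (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
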