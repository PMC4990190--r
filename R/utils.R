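# internal helpers shared across modules

stopf <- function(fmt, ..., class = "diplacusr_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "diplacusr_error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x))
    stopf("'%s' must be a single finite number", name, class = "validation_error")
  low_ok  <- if (strict_lower) x > lower else x >= lower
  high_ok <- if (strict_upper) x < upper else x <= upper
  if (!low_ok || !high_ok)
    stopf("'%s' = %g is outside its admissible range", name, x,
          class = "validation_error")
  invisible(x)
}

# Linear interpolation on a log2-frequency axis with constant extrapolation
# beyond the anchors; the standard audiological convention for octave-scaled
# quantities.  A single anchor yields a constant map.
log2_interp <- function(freqs, values, at) {
  if (length(freqs) == 1L) return(rep(values, length(at)))
  stats::approx(x = log2(freqs), y = values, xout = log2(at),
                method = "linear", rule = 2)$y
}

other_ear <- function(ear) if (identical(ear, "left")) "right" else "left"

check_ear <- function(ear, name = "ear") {
  if (!is.character(ear) || length(ear) != 1L || !ear %in% c("left", "right"))
    stopf("'%s' must be \"left\" or \"right\"", name, class = "validation_error")
  ear
}
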