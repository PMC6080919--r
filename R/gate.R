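#' Kinetochore binding-rate gate (F-actin patch surrogate)
#'
#' Piecewise-constant, right-continuous multiplier in \[0, 1\] applied to the
#' kinetochore-microtubule binding rate, standing in for the steric block by
#' Arp2/3-nucleated F-actin patches. The default matches the patch
#' disassembly kinetics: binding blocked for the first 4 min after NEBD,
#' then stepped to 10, 30, 70 and 100% at minutes 4, 5, 6 and 7 so the ramp
#' spans 4-8 min after NEBD. An alternative convention with the increments
#' applied at minutes 5-8 is available via `first_step_at = 5`.
#'
#' @param breakpoints Two-column data frame (or tibble) with columns `time`
#'   (min after NEBD) and `fraction` in \[0, 1\]; the gate takes value
#'   `fraction[i]` on `[time[i], time[i+1])`. Value before the first
#'   breakpoint is 0.
#' @param first_step_at Convenience for the default ramp: minute at which
#'   the first (10%) increment is applied (4, the default, or 5).
#' @return An object of class `gate_schedule`.
#' @examples
#' g <- gate_schedule()
#' gate_value(c(2, 6.5, 10), g) # 0.0 0.7 1.0
#' @export
gate_schedule <- function(breakpoints = NULL, first_step_at = 4) {
  if (is.null(breakpoints)) {
    breakpoints <- data.frame(
      time = first_step_at - 4 + c(0, 4, 5, 6, 7),
      fraction = c(0, 0.10, 0.30, 0.70, 1.00)
    )
  }
  breakpoints <- as.data.frame(breakpoints)
  if (!all(c("time", "fraction") %in% names(breakpoints))) {
    stop("`breakpoints` needs columns `time` and `fraction`", call. = FALSE)
  }
  bp <- breakpoints[order(breakpoints$time), c("time", "fraction")]
  if (any(!is.finite(bp$time)) || any(!is.finite(bp$fraction))) {
    stop("gate breakpoints must be finite", call. = FALSE)
  }
  if (any(bp$fraction < 0 | bp$fraction > 1)) {
    stop("gate fractions must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(bp$fraction)) {
    stop("gate fractions must be monotone nondecreasing", call. = FALSE)
  }
  if (anyDuplicated(bp$time)) {
    stop("gate breakpoint times must be distinct", call. = FALSE)
  }
  structure(list(time = bp$time, fraction = bp$fraction),
            class = "gate_schedule")
}

#' Constant-one gate (variants 1 and 2)
#' @return A `gate_schedule` equal to 1 for all t >= 0.
#' @export
gate_constant <- function() {
  gate_schedule(data.frame(time = 0, fraction = 1))
}

#' Evaluate the binding-rate gate
#'
#' @param t Time(s) in minutes after NEBD (vectorized).
#' @param schedule A [gate_schedule()].
#' @return Numeric vector of gate fractions in \[0, 1\] (right-continuous
#'   piecewise-constant lookup; 0 before the first breakpoint).
#' @export
gate_value <- function(t, schedule = gate_schedule()) {
  stopifnot(inherits(schedule, "gate_schedule"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  idx <- findInterval(t, schedule$time)
  out <- numeric(length(t))
  out[idx > 0] <- schedule$fraction[idx[idx > 0]]
  out
}

#' @export
print.gate_schedule <- function(x, ...) {
  cat("<gate_schedule>\n")
  for (i in seq_along(x$time)) {
    cat(sprintf("  t >= %g min: %.0f%%\n", x$time[i], 100 * x$fraction[i]))
  }
  invisible(x)
}
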