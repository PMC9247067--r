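#' Applied-voltage waveforms
#'
#' Constructors for the waveform shapes used by capacitively coupled
#' stimulation rigs. Every waveform knows its exact value ([wf_value()]) and
#' analytic slope ([wf_slope()]), its matched-frequency reduction
#' ([matched_frequency()], [matched_amplitude()]) and can be sampled to a
#' piecewise-linear form ([as_pwl()]).
#'
#' * `wf_sinusoid(amplitude, frequency, phase)`: `A*sin(2*pi*f*t + phase)`.
#' * `wf_trapezoid(amplitude, rise, width, fall, polarity, period)`: a linear
#'   ramp from 0 to `polarity*amplitude` over `rise`, a plateau of duration
#'   `width`, a ramp back over `fall`; zero outside the pulse, or repeated
#'   every `period` seconds if one is given.
#' * `wf_sawtooth(peak_to_peak, rise, fall)`: periodic asymmetric sawtooth,
#'   zero-mean, rising from `-pp/2` to `+pp/2` over `rise` and falling back
#'   over `fall`; period `rise + fall`.
#' * `wf_pwl(t, v)`: piecewise-linear interpolation of breakpoints, defined
#'   only on `[min(t), max(t)]`.
#' * `wf_dc(level)`: constant potential.
#'
#' @param amplitude,level Volts.
#' @param frequency Hz, `> 0`.
#' @param phase Radians.
#' @param rise,fall,width,period Seconds; rise and fall must be `> 0`.
#' @param polarity `+1` or `-1`.
#' @param peak_to_peak Volts, full swing of the sawtooth.
#' @param t,v Breakpoint times (strictly increasing, seconds) and values
#'   (volts).
#' @return An object of class `cc_waveform`.
#' @name waveforms
NULL

new_waveform <- function(variant, fields, pwl_kind) {
  structure(c(list(variant = variant), fields),
            class = c(paste0("cc_wf_", variant), "cc_waveform"),
            pwl_kind = pwl_kind)
}

#' @rdname waveforms
#' @export
wf_sinusoid <- function(amplitude, frequency, phase = 0) {
  stopifnot(is.finite(amplitude), is.finite(frequency), frequency > 0,
            is.finite(phase))
  new_waveform("sinusoid",
               list(amplitude = amplitude, frequency = frequency, phase = phase),
               pwl_kind = FALSE)
}

#' @rdname waveforms
#' @export
wf_trapezoid <- function(amplitude, rise, width, fall = rise, polarity = 1,
                         period = NULL) {
  stopifnot(is.finite(amplitude), rise > 0, fall > 0, width >= 0,
            polarity %in% c(-1, 1))
  total <- rise + width + fall
  if (!is.null(period)) stopifnot(period >= total)
  new_waveform("trapezoid",
               list(amplitude = amplitude, rise = rise, width = width,
                    fall = fall, polarity = polarity, period = period,
                    total = total),
               pwl_kind = TRUE)
}

#' @rdname waveforms
#' @export
wf_sawtooth <- function(peak_to_peak, rise, fall) {
  stopifnot(peak_to_peak > 0, rise > 0, fall > 0)
  new_waveform("sawtooth",
               list(peak_to_peak = peak_to_peak, rise = rise, fall = fall,
                    period = rise + fall),
               pwl_kind = TRUE)
}

#' @rdname waveforms
#' @export
wf_pwl <- function(t, v) {
  stopifnot(length(t) >= 2L, length(t) == length(v),
            all(is.finite(t)), all(is.finite(v)))
  if (any(diff(t) <= 0))
    stop("piecewise-linear breakpoints must be strictly increasing in t",
         call. = FALSE)
  new_waveform("pwl", list(t = as.numeric(t), v = as.numeric(v)),
               pwl_kind = TRUE)
}

#' @rdname waveforms
#' @export
wf_dc <- function(level) {
  stopifnot(is.finite(level))
  new_waveform("constant_dc", list(level = level), pwl_kind = FALSE)
}

#' @export
print.cc_waveform <- function(x, ...) {
  desc <- switch(x$variant,
    sinusoid = sprintf("sinusoid %.6g V, %.6g Hz, phase %.3g rad",
                       x$amplitude, x$frequency, x$phase),
    trapezoid = sprintf("trapezoid pulse %+.6g V, rise %.3g s, width %.3g s, fall %.3g s%s",
                        x$polarity * x$amplitude, x$rise, x$width, x$fall,
                        if (is.null(x$period)) "" else sprintf(", period %.3g s", x$period)),
    sawtooth = sprintf("asymmetric sawtooth %.6g V pk-pk, rise %.3g s, fall %.3g s",
                       x$peak_to_peak, x$rise, x$fall),
    pwl = sprintf("piecewise linear, %d breakpoints on [%.3g, %.3g] s",
                  length(x$t), x$t[1], x$t[length(x$t)]),
    constant_dc = sprintf("constant DC %.6g V", x$level))
  cat("<cc_waveform>", desc, "\n")
  invisible(x)
}

#' Evaluate a waveform (volts)
#'
#' Vectorised over `t`. Periodic variants extend over all time; a one-shot
#' trapezoid is zero outside its pulse; a piecewise-linear waveform errors
#' outside its breakpoint span.
#'
#' @param w A waveform (see [waveforms]).
#' @param t Time(s) in seconds.
#' @export
wf_value <- function(w, t) UseMethod("wf_value")

#' Slope of a waveform (volts per second)
#'
#' The exact analytic derivative; piecewise-constant and right-continuous at
#' breakpoints for the edged variants (at the final breakpoint of a
#' piecewise-linear span the last segment's slope is returned).
#'
#' @inheritParams wf_value
#' @export
wf_slope <- function(w, t) UseMethod("wf_slope")

#' @export
wf_value.cc_wf_sinusoid <- function(w, t)
  w$amplitude * sin(2 * pi * w$frequency * t + w$phase)

#' @export
wf_slope.cc_wf_sinusoid <- function(w, t)
  2 * pi * w$frequency * w$amplitude * cos(2 * pi * w$frequency * t + w$phase)

#' @export
wf_value.cc_wf_constant_dc <- function(w, t) rep(w$level, length(t))

#' @export
wf_slope.cc_wf_constant_dc <- function(w, t) rep(0, length(t))

trap_local <- function(w, t) {
  if (!is.null(w$period)) t <- t %% w$period
  t
}

#' @export
wf_value.cc_wf_trapezoid <- function(w, t) {
  tl <- trap_local(w, t)
  A <- w$polarity * w$amplitude
  v <- numeric(length(t))
  up <- tl >= 0 & tl < w$rise
  flat <- tl >= w$rise & tl < w$rise + w$width
  down <- tl >= w$rise + w$width & tl < w$total
  v[up] <- A * tl[up] / w$rise
  v[flat] <- A
  v[down] <- A * (w$total - tl[down]) / w$fall
  v
}

#' @export
wf_slope.cc_wf_trapezoid <- function(w, t) {
  tl <- trap_local(w, t)
  A <- w$polarity * w$amplitude
  s <- numeric(length(t))
  s[tl >= 0 & tl < w$rise] <- A / w$rise
  s[tl >= w$rise + w$width & tl < w$total] <- -A / w$fall
  s
}

#' @export
wf_value.cc_wf_sawtooth <- function(w, t) {
  tl <- t %% w$period
  A <- w$peak_to_peak
  ifelse(tl < w$rise, -A / 2 + A * tl / w$rise,
         A / 2 - A * (tl - w$rise) / w$fall)
}

#' @export
wf_slope.cc_wf_sawtooth <- function(w, t) {
  tl <- t %% w$period
  ifelse(tl < w$rise, w$peak_to_peak / w$rise, -w$peak_to_peak / w$fall)
}

check_pwl_span <- function(w, t) {
  if (any(t < w$t[1] - 1e-12 | t > w$t[length(w$t)] + 1e-12))
    stop(sprintf("time out of range: piecewise-linear waveform is defined on [%g, %g] s",
                 w$t[1], w$t[length(w$t)]), call. = FALSE)
}

#' @export
wf_value.cc_wf_pwl <- function(w, t) {
  check_pwl_span(w, t)
  stats::approx(w$t, w$v, xout = t, rule = 2)$y
}

#' @export
wf_slope.cc_wf_pwl <- function(w, t) {
  check_pwl_span(w, t)
  slopes <- diff(w$v) / diff(w$t)
  idx <- findInterval(t, w$t, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(slopes))
  slopes[idx]
}

#' Matched frequency of a waveform (Hz)
#'
#' The frequency of the sinusoid whose maximum slew rate equals the
#' waveform's: equating `A/tau = 2*pi*f*A` for a linear ramp of amplitude `A`
#' and edge duration `tau` gives `f = 1/(2*pi*tau)`. For edged waveforms
#' `tau` is the *shortest* edge (the one with the largest `|dV/dt|`); for a
#' sinusoid the rule is an identity and returns its own frequency; for a
#' general piecewise-linear waveform `f = max|slope| / (2*pi*max|v|)`; DC has
#' no edge and returns 0. A flat nonzero piecewise-linear waveform returns 0
#' with a warning.
#'
#' @inheritParams wf_value
#' @return Frequency in Hz.
#' @examples
#' matched_frequency(wf_trapezoid(1750, rise = 1.85e-3, width = 0.1))  # 86.03 Hz
#' matched_frequency(wf_sawtooth(100, rise = 45e-9, fall = 62.5e-3))   # 3.5 MHz
#' @export
matched_frequency <- function(w) UseMethod("matched_frequency")

#' @export
matched_frequency.cc_wf_sinusoid <- function(w) w$frequency

#' @export
matched_frequency.cc_wf_constant_dc <- function(w) 0

#' @export
matched_frequency.cc_wf_trapezoid <- function(w) 1 / (2 * pi * min(w$rise, w$fall))

#' @export
matched_frequency.cc_wf_sawtooth <- function(w) 1 / (2 * pi * min(w$rise, w$fall))

#' @export
matched_frequency.cc_wf_pwl <- function(w) {
  smax <- max(abs(diff(w$v) / diff(w$t)))
  vmax <- max(abs(w$v))
  if (smax == 0 || vmax == 0) {
    warning("waveform has no edges; matched frequency is 0", call. = FALSE)
    return(0)
  }
  smax / (2 * pi * vmax)
}

#' Amplitude paired with the matched frequency (volts)
#'
#' The `A` of the matched sinusoid: the full edge swing for trapezoid and
#' sawtooth waveforms, the waveform's own amplitude for a sinusoid, the
#' largest absolute breakpoint value for piecewise-linear data, and the level
#' for DC.
#'
#' @inheritParams wf_value
#' @export
matched_amplitude <- function(w) UseMethod("matched_amplitude")

#' @export
matched_amplitude.cc_wf_sinusoid <- function(w) abs(w$amplitude)

#' @export
matched_amplitude.cc_wf_constant_dc <- function(w) abs(w$level)

#' @export
matched_amplitude.cc_wf_trapezoid <- function(w) abs(w$amplitude)

#' @export
matched_amplitude.cc_wf_sawtooth <- function(w) w$peak_to_peak

#' @export
matched_amplitude.cc_wf_pwl <- function(w) max(abs(w$v))

#' Convert a waveform to its piecewise-linear form
#'
#' Every analytic breakpoint of the source waveform is kept exactly (no edge
#' is smeared); the sinusoid is sampled uniformly. A piecewise-linear
#' waveform round-trips unchanged.
#'
#' @inheritParams wf_value
#' @param samples_per_period Samples per period for smooth variants, `> 0`.
#' @param span Time span `c(t0, t1)` to cover; defaults to one period (one
#'   pulse for a one-shot trapezoid, `[0, 1]` s for DC).
#' @return A [wf_pwl()] waveform.
#' @export
as_pwl <- function(w, samples_per_period = 64L, span = NULL) {
  stopifnot(inherits(w, "cc_waveform"))
  if (samples_per_period <= 0)
    stop("samples_per_period must be positive", call. = FALSE)
  if (w$variant == "pwl") return(w)
  if (is.null(span)) {
    span <- switch(w$variant,
      sinusoid = c(0, 1 / w$frequency),
      trapezoid = c(0, if (is.null(w$period)) w$total else w$period),
      sawtooth = c(0, w$period),
      constant_dc = c(0, 1))
  }
  if (w$variant == "sinusoid") {
    t <- seq(span[1], span[2], length.out = max(2L, ceiling(
      samples_per_period * (span[2] - span[1]) * w$frequency) + 1L))
  } else {
    t <- sort(unique(c(span, wf_breakpoints(w, span))))
  }
  wf_pwl(t, wf_value(w, t))
}

# Breakpoint times of a waveform inside [span[1], span[2]] (excluding the
# span ends); empty for smooth variants.
wf_breakpoints <- function(w, span) {
  bp <- switch(w$variant,
    trapezoid = {
      base <- c(0, w$rise, w$rise + w$width, w$total)
      if (is.null(w$period)) base
      else {
        ks <- floor(span[1] / w$period):ceiling(span[2] / w$period)
        as.vector(outer(base, ks * w$period, `+`))
      }
    },
    sawtooth = {
      ks <- floor(span[1] / w$period):ceiling(span[2] / w$period)
      as.vector(outer(c(0, w$rise), ks * w$period, `+`))
    },
    pwl = w$t,
    numeric(0))
  bp[bp > span[1] & bp < span[2]]
}

# TRUE for waveforms whose slope is piecewise constant between breakpoints.
wf_is_pwl_kind <- function(w) isTRUE(attr(w, "pwl_kind"))

# Fundamental period, NA when not periodic.
wf_period <- function(w) {
  switch(w$variant,
    sinusoid = 1 / w$frequency,
    sawtooth = w$period,
    trapezoid = if (is.null(w$period)) NA_real_ else w$period,
    NA_real_)
}
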