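#' Resistance of a layer (ohm)
#'
#' `R = l / (sigma * A)`: the axial resistance of a uniform slab. A perfect
#' insulator (`sigma = 0`) returns `Inf`, the open-branch sentinel the rest of
#' the impedance math treats as "no resistive path", never an error.
#'
#' @param layer A [layer()] object.
#' @param area Cross-sectional area in m^2, `> 0`.
#' @return Resistance in ohm (possibly `Inf`).
#' @export
layer_resistance <- function(layer, area) {
  check_area(area)
  sigma <- layer$material$conductivity
  if (sigma == 0) return(Inf)
  layer$thickness / (sigma * area)
}

#' Capacitance of a layer (farad)
#'
#' `C = eps0 * eps_r * A / l`, the parallel-plate capacitance of the slab.
#'
#' @inheritParams layer_resistance
#' @return Capacitance in farad, always finite and positive since `eps_r >= 1`.
#' @export
layer_capacitance <- function(layer, area) {
  check_area(area)
  cc_eps0 * layer$material$rel_permittivity * area / layer$thickness
}

check_area <- function(area) {
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0)
    stop("invalid geometry: area must be a finite number > 0", call. = FALSE)
  invisible(area)
}

#' Capacitive reactance (ohm, negative sign convention)
#'
#' `X_c = -1 / (omega * C)` with `omega = 2*pi*frequency`. Stored negative:
#' the capacitor's impedance is `j * X_c`. At `frequency = 0` the branch is
#' open and the reactance is `-Inf`.
#'
#' @param capacitance Capacitance in farad, `> 0`.
#' @param frequency Frequency in Hz, `>= 0`.
#' @return Reactance in ohm, `<= 0`.
#' @export
capacitive_reactance <- function(capacitance, frequency) {
  stopifnot(capacitance > 0, frequency >= 0)
  if (frequency == 0) return(-Inf)
  -1 / (2 * pi * frequency * capacitance)
}

#' Impedance of one parallel-RC layer (complex ohm)
#'
#' Parallel combination `1/Z = 1/R + j*omega*C`. Evaluated through the
#' admittance so the open-branch sentinels compose cleanly:
#' * `R = Inf` (perfect insulator): `Z = -j/(omega*C)` exactly;
#' * `frequency = 0`: `Z = R` (open capacitor branch);
#' * both: `Z = Inf + 0i`, the open-circuit sentinel (documented, no error).
#'
#' @param resistance Resistance in ohm (possibly `Inf`).
#' @param capacitance Capacitance in farad, `> 0`.
#' @param frequency Frequency in Hz, `>= 0`.
#' @return Complex impedance in ohm.
#' @export
layer_impedance <- function(resistance, capacitance, frequency) {
  stopifnot(frequency >= 0, capacitance > 0)
  G <- if (is.infinite(resistance)) 0 else 1 / resistance
  Y <- complex(real = G, imaginary = 2 * pi * frequency * capacitance)
  if (Mod(Y) == 0) return(complex(real = Inf, imaginary = 0))
  1 / Y
}

# Per-layer component values and complex impedances for a ladder at one
# frequency.  Returns vectors; Z is Inf+0i for fully open branches (f = 0 and
# G = 0), which solve_stack_phasor handles as an open circuit.
ladder_impedances <- function(lad, frequency) {
  w <- 2 * pi * frequency
  Y <- complex(real = lad$G, imaginary = w * lad$C)
  Z <- ifelse(Mod(Y) == 0, complex(real = Inf, imaginary = 0), 1 / Y)
  R <- ifelse(lad$G == 0, Inf, 1 / lad$G)
  X <- ifelse(w * lad$C > 0, -1 / (w * lad$C), -Inf)
  list(R = R, C = lad$C, X = X, Z = Z)
}

#' Solve the layered stack in the phasor domain
#'
#' Treats the stack as a series ladder of parallel-RC layers at a single
#' frequency: `Z_total = sum(Z_i)`, `V_i = (Z_i / Z_total) * V`, and
#' `|E_i| = |V_i| / l_i`. The applied phasor is `amplitude + 0i`, so layer
#' phases are phases relative to the source.
#'
#' Two ladder models are available. `"full"` keeps both branches of every
#' layer, electrodes included, so the DC limit is a genuine resistive divider.
#' `"reduced"` is the classic three-component approximation: electrodes
#' dropped, insulators as pure capacitors, medium as a pure resistor. With
#' highly conductive electrodes the two differ by well under 0.1%.
#'
#' At `frequency = 0` a capacitively coupled stack passes (almost) no current:
#' when the computed medium field falls below `eps_zero` the estimate is
#' flagged `effectively_zero`, reconciling the finite resistive-divider value
#' of the full model with the physical statement that DC stimulation induces
#' essentially no field in the medium. If the reduced model is fully open at
#' DC (pure capacitors at zero frequency) the current is exactly zero, the
#' medium field is 0 and the source voltage appears across the open insulator
#' branches via their series-capacitance divider.
#'
#' @param stack A [stack_setup()] object.
#' @param amplitude Applied voltage amplitude in volts (real).
#' @param frequency Frequency in Hz, `>= 0`.
#' @param model `"full"` (default) or `"reduced"`.
#' @param eps_zero Threshold in V/m for the effectively-zero flag (default
#'   `1e-9`).
#' @return An object of class `cc_estimate`: a list with the per-layer table
#'   (`layers`: name, role, thickness, R, C, X, complex Z and V, `E_V_per_m`,
#'   `phase_rad`), `Z_total`, `E_medium` (V/m), `phase_lead_medium` (rad),
#'   `effectively_zero`, `method`, `model`, `frequency`, `amplitude`.
#' @examples
#' s <- build_setup("brighton1992")
#' est <- solve_stack_phasor(s, amplitude = 44.81, frequency = 60e3)
#' est$E_medium  # ~2.1 V/m
#' @export
solve_stack_phasor <- function(stack, amplitude, frequency,
                               model = c("full", "reduced"),
                               eps_zero = 1e-9) {
  model <- match.arg(model)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  stopifnot(is.numeric(frequency), length(frequency) == 1L, frequency >= 0)
  lad <- stack_ladder(stack, model)
  imp <- ladder_impedances(lad, frequency)
  n <- length(lad$G)
  open <- is.infinite(Re(imp$Z))
  if (any(open)) {
    # zero current: no drop across finite layers, source divides over the
    # open branches in inverse proportion to their capacitance
    V <- complex(real = numeric(n))
    inv_c <- ifelse(open, 1 / lad$C, 0)
    V[open] <- amplitude * inv_c[open] / sum(inv_c)
    Z_total <- complex(real = Inf)
  } else {
    Z_total <- sum(imp$Z)
    V <- amplitude * imp$Z / Z_total
  }
  E <- Mod(V) / lad$l
  est <- structure(list(
    method = if (model == "full") "phasor_full" else "phasor_reduced",
    model = model,
    frequency = frequency,
    amplitude = amplitude,
    layers = data.frame(
      name = lad$name, role = lad$role, thickness_m = lad$l,
      R_ohm = imp$R, C_farad = imp$C, X_ohm = imp$X,
      Z = imp$Z, V = V, E_V_per_m = E, phase_rad = Arg(V),
      stringsAsFactors = FALSE
    ),
    Z_total = Z_total,
    E_medium = E[lad$medium],
    phase_lead_medium = Arg(V[lad$medium]),
    eps_zero = eps_zero,
    effectively_zero = E[lad$medium] < eps_zero
  ), class = "cc_estimate")
  est
}

#' @export
print.cc_estimate <- function(x, ...) {
  cat(sprintf("<cc_estimate %s>  f = %.6g Hz, amplitude = %.6g V\n",
              x$method, x$frequency, x$amplitude))
  tab <- x$layers
  tab$`|Z|_ohm` <- Mod(tab$Z)
  tab$`|V|_volt` <- Mod(tab$V)
  print(tab[, c("name", "role", "R_ohm", "C_farad", "X_ohm",
                "|Z|_ohm", "|V|_volt", "E_V_per_m", "phase_rad")],
        row.names = FALSE, digits = 4)
  cat(sprintf("E_medium = %.6g V/m%s (phase lead %.2f deg)\n", x$E_medium,
              if (isTRUE(x$effectively_zero)) " [effectively zero]" else "",
              x$phase_lead_medium * 180 / pi))
  invisible(x)
}

#' Capacitor-only quick estimate of the medium field
#'
#' In the usual regime the insulator impedances dominate the whole stack
#' (`Z_r,medium << Z_c,insulators`), so the circuit responds as the series
#' combination of the insulator capacitances: `I = C_series * dV/dt` and the
#' medium field is `E = I * R_medium / l_medium = I / (sigma_medium * A)`.
#' This is the back-of-envelope displacement-current estimate; it is linear
#' in the slew rate and needs no phasor solve.
#'
#' The regime assumption is checked when the stack carries a waveform with a
#' defined matched frequency: if the medium's resistive impedance is not small
#' (< 5%) against the series insulator reactance at that frequency a warning
#' is emitted (never an error).
#'
#' @param stack A [stack_setup()] object.
#' @param dV_dt Applied voltage slew rate in V/s.
#' @return Medium field estimate in V/m (signed like `dV_dt`).
#' @examples
#' s <- build_setup("hartig2000")
#' quick_capacitive_estimate(s, dV_dt = 100 / 45e-9)  # ~5.5 V/m
#' @export
quick_capacitive_estimate <- function(stack, dV_dt) {
  stopifnot(is.numeric(dV_dt), length(dV_dt) == 1L, is.finite(dV_dt))
  lad <- stack_ladder(stack, "full")
  ins <- lad$role == "insulator"
  if (!any(ins))
    stop("stack has no insulator layer: quick estimate undefined", call. = FALSE)
  C_series <- 1 / sum(1 / lad$C[ins])
  m <- lad$medium
  R_m <- if (lad$G[m] == 0) Inf else 1 / lad$G[m]
  if (!is.null(stack$waveform)) {
    f <- tryCatch(matched_frequency(stack$waveform), warning = function(w) NA_real_)
    if (is.finite(f) && f > 0) {
      X_series <- 1 / (2 * pi * f * C_series)
      if (is.infinite(R_m) || R_m > 0.05 * X_series)
        warning("medium resistance is not small against the insulator reactance; ",
                "the capacitor-only regime assumption (Z_r << Z_c) is violated",
                call. = FALSE)
    }
  }
  I <- C_series * dV_dt
  I * R_m / lad$l[m]
}

#' Dense linear-system solution of the ladder (verification oracle)
#'
#' Solves the same series ladder as [solve_stack_phasor()] but as one dense
#' complex linear system: the unknowns are the per-layer voltage drops, the
#' equations are current continuity through each layer admittance
#' (`Y_i V_i = Y_{i+1} V_{i+1}`) plus the source loop equation
#' (`sum(V_i) = V`), each continuity row equilibrated by its largest
#' admittance so metallic electrodes (admittances ~1e8 S beside ~1e-12 S
#' insulators) do not wreck the conditioning. The tiny medium drop is a
#' direct unknown, never the difference of two near-equal potentials.
#' Intended for cross-checking in tests; it shares no code path with
#' [solve_stack_phasor()] beyond the layer parameter extraction.
#'
#' @inheritParams solve_stack_phasor
#' @return A list with complex per-layer drops `V`, `E` magnitudes (V/m) and
#'   `E_medium`.
#' @export
phasor_oracle <- function(stack, amplitude, frequency, model = c("full", "reduced")) {
  model <- match.arg(model)
  lad <- stack_ladder(stack, model)
  w <- 2 * pi * frequency
  Y <- complex(real = lad$G, imaginary = w * lad$C)
  n <- length(Y)
  if (any(Mod(Y) == 0))
    stop("numerical error: open branch makes the linear system singular", call. = FALSE)
  if (n == 1L) {
    V <- complex(real = amplitude)
  } else {
    Amat <- matrix(complex(real = 0), n, n)
    b <- complex(real = numeric(n))
    for (i in seq_len(n - 1L)) {
      s <- 1 / max(Mod(Y[i]), Mod(Y[i + 1L]))
      Amat[i, i] <- s * Y[i]
      Amat[i, i + 1L] <- -s * Y[i + 1L]
    }
    Amat[n, ] <- complex(real = 1)
    b[n] <- amplitude
    V <- solve(Amat, b)
  }
  E <- Mod(V) / lad$l
  list(V = V, E = E, E_medium = E[lad$medium])
}
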