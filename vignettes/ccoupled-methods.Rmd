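---
title: "Estimating the electric field in capacitively coupled stimulation setups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the electric field in capacitively coupled stimulation setups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccoupled)
```

## The physical model

In a capacitively coupled (CCoupled) stimulation rig two metal plates face
each other across a sandwich of insulating layers (plastic, glass, air) and
the conductive culture medium that holds the cells. Because no charge can
cross the insulators, only displacement current flows, and the electric field
induced in the medium is a small, strongly frequency-dependent fraction of
the applied voltage. `ccoupled` models the rig as a coaxial cylinder of
uniform cross-section $A = \pi r^2$: charge moves along the axis, the field
inside each layer is uniform, and every layer $i$ behaves as a resistor and a
capacitor in parallel,

$$R_i = \rho_i \frac{l_i}{A}, \qquad C_i = \frac{\varepsilon_0 \varepsilon_{r,i} A}{l_i},$$

with $\rho_i = 1/\sigma_i$ the resistivity, $\varepsilon_{r,i}$ the relative
permittivity, and $l_i$ the thickness. At angular frequency
$\omega = 2\pi f$ the layer's admittance is $1/Z_i = 1/R_i + j\omega C_i$,
the layers are in series, and the medium field follows from the complex
voltage divider

$$Z_\mathrm{total} = \sum_i Z_i, \qquad
  V_i = \frac{Z_i}{Z_\mathrm{total}}\,V, \qquad
  |E_i| = \frac{|V_i|}{l_i}.$$

Because every impedance scales as $1/A$, the fields are independent of the
cross-sectional area; and as long as the medium's resistive impedance is far
below the insulators' capacitive impedance ($Z_r \ll Z_c$), the medium field
is also nearly independent of the medium height and leads the source by close
to 90 degrees. Both statements are enforced as tests.

Three estimation routes are provided and must agree with one another:

1. **Phasor solve** (`solve_stack_phasor()`), at a single frequency, either
   with all five layers (`model = "full"`) or with the classic three-element
   reduction (`model = "reduced"`: insulators as pure capacitors, medium as
   a pure resistor, electrodes dropped).
2. **Quick capacitive estimate** (`quick_capacitive_estimate()`): in the
   $Z_r \ll Z_c$ regime the stack responds as the series insulator
   capacitance $C_s$, so $I = C_s\,\mathrm{d}V/\mathrm{d}t$ and
   $E = I R_m / l_m$. Linear in the slew rate, no complex arithmetic.
3. **Transient simulation** (`simulate_transient()`), integrating the ladder
   under the real waveform.

## Arbitrary waveforms and the matched frequency

The phasor method needs a single frequency. For edged waveforms
(trapezoidal pulses, sawtooths, piecewise-linear captures) the package uses
the slew-rate matching rule: a sinusoid of amplitude $A$ and frequency $f$
has maximum slope $2\pi f A$, so equating it with a linear ramp of amplitude
$A$ and edge time $\tau$ gives

$$f = \frac{1}{2\pi\tau}.$$

Conventions, chosen once and used everywhere:

* when rise and fall differ, the **shortest** edge (largest $|dV/dt|$)
  defines $\tau$ — a 45 ns rise beside a 62.5 ms fall is matched at 3.5 MHz;
* the paired amplitude is the full edge swing (peak-to-peak for a sawtooth,
  the pulse amplitude for a trapezoid), the amplitude of the sinusoid for a
  sinusoid, and $\max|v|$ for sampled waveforms, where the rule generalises
  to $f = \max|\dot v| / (2\pi \max|v|)$;
* DC has matched frequency 0; a flat, edge-free sampled waveform returns 0
  with a warning;
* waveform derivatives are right-continuous at breakpoints so transient
  stepping is deterministic.

## The transient solver

The time-domain module integrates the ladder's capacitor voltages $v_i$ with
the common current eliminated algebraically,

$$I = \frac{\dot V + \sum_j v_j G_j / C_j}{\sum_j 1/C_j}, \qquad
  \dot v_i = \frac{I - G_i v_i}{C_i},$$

and reconstructs one non-medium layer as $v_N = V(t) - \sum_{i<N} v_i$, so
Kirchhoff's voltage law holds to machine precision at every output point
(the reported residuals are at rounding level). Numerical choices that
matter:

* **Electrodes are excluded from the simulated ladder.** A metallic layer
  relaxes at $G/C \sim 10^{19}\,\mathrm{s^{-1}}$; together with insulator
  rates of $10^{-3}\,\mathrm{s^{-1}}$ that is a wider eigenvalue spread than
  double precision can represent, while the electrode drop itself is a
  $\sim 10^{-9}$ fraction of the source. The phasor solution retains the
  electrodes and shows their effect on the medium field is below 0.1%.
* **TR-BDF2 stepping.** The remaining system is still stiff (the medium
  relaxes in picoseconds to nanoseconds against drive periods up to
  seconds), so an implicit, L-stable one-step scheme is mandatory; the
  trapezoidal rule alone is A-stable but rings at waveform corners. With
  $\gamma = 2 - \sqrt{2}$ both stages share one small matrix factorisation
  per mesh segment.
* **Breakpoint alignment and edge resolution.** Mesh points land exactly on
  every waveform breakpoint, and each segment of an edged waveform gets at
  least 20 steps (`min_edge_steps`), so a 45 ns edge inside a 62.5 ms period
  cannot be skipped.
* **Boundary-layer substeps.** A slope discontinuity excites the fast mode;
  the first step of each segment is split into geometrically growing
  substeps (ratio 1.5) starting below the fastest system time constant,
  because TR-BDF2's stability function dips slightly negative for moderately
  stiff steps and an unresolved layer would appear as a spurious ~10% peak.
* **Initial condition** is the DC steady state for $V(t_0)$ (the resistive
  divider; for ideal $\sigma = 0$ insulators, a series-capacitance divider
  across the open branches), which suppresses start-up transients.
* **Problem sizes.** Steady-state comparisons simulate 10 drive periods at
  256 steps per period and fit $a\sin\omega t + b\cos\omega t$ over the last
  two periods by least squares; every fixture run stays below $10^5$ steps.
  Halving the step changes fitted amplitudes by well under 0.1%.

## Degenerate inputs and sign conventions

* $\sigma = 0$ is a legal perfect insulator: the resistive branch is an open
  sentinel (`R = Inf`), never a division error. At $f = 0$ a capacitor
  branch is open; if both branches are open the impedance is the documented
  open-circuit sentinel.
* Capacitive reactance is stored negative ($X_c = -1/(\omega C)$), matching
  the convention in which a capacitor's impedance is $jX_c$.
* $\varepsilon_0$ is fixed at the CODATA value
  $8.8541878128\times 10^{-12}$ F/m.
* **DC and the effectively-zero flag.** Under constant voltage the interface
  charge cancels the applied field in the medium, so the C-R-C reduction
  gives exactly zero at $f = 0$. The full model keeps the insulators'
  finite literature conductivities and yields a genuine resistive-divider
  value instead (e.g. $3.7\times10^{-10}$ V/m for a 14.2 V DC fixture); any
  medium field below the configurable `eps_zero` ($10^{-9}$ V/m) is flagged
  `effectively_zero` so both answers read as the physical "no field".

## The packaged setups

Eight published stimulation rigs ship as YAML fixtures (`build_setup()`),
with the field values their authors reported (`cc_reported()`) and the
audit verdict per setup (`setup_entry()`). Literature-derived assumptions
are baked into the fixtures exactly as documented in each entry's notes:
spec-sheet rise times of 7 ns and 45 ns for the two pulse generators, a
1 mm petri wall where the original study reported none, a 22 Hz / 100 mV
stand-in sinusoid for a damped "degenerate wave" whose shape is not
parameterised here, and cylindrical equivalents for three rigs whose real
geometry is not coaxial. `run_reproduce()` regenerates the audit: the
verdict uses an agreement band of a factor of 2, which cleanly separates
the published agreement cases (within ~40%) from the disagreement cases
(10x to 8 orders of magnitude).

One fixture-level quirk: the published component table duplicates the
polystyrene capacitance and reactance into the medium row of one setup (a
typesetting slip), so the packaged reference stores those two cells as
missing and checks only the medium resistance there.

## Synthetic stacks for property testing

`random_stack()` draws 3-7 layer stacks with exactly one conductive medium
(0.5-2 S/m) among insulators ($10^{-14}$-$10^{-12}$ S/m, log-uniform),
thicknesses 0.1-50 mm, permittivities 1-90 and radii 5-70 mm — the
parameter ranges spanned by the packaged rigs. These drive the property
suites: voltage conservation, area invariance, and the equivalence of the
series-divider solution with an independent dense linear-system oracle. The
generator emulates the *electrical* diversity of real rigs, not their
geometric quirks: curved electrodes, fringing fields, scaffold-induced
inhomogeneity and electrode polarisation are outside the model, so passing
tests validate the circuit abstraction, not the fidelity of that
abstraction to any particular bench setup.

## Known limitations

* Coaxial, uniform-section geometry only; no finite-element stage. For
  rigs far from cylindrical the estimates remain order-of-magnitude guides
  provided insulator thicknesses are preserved.
* Dielectrics are linear and frequency-independent; no electrode
  polarisation impedance, no temperature effects.
* The quasi-electrostatic approximation is assumed throughout (no wave
  propagation or induction).
* Waveforms are deterministic shapes; there is no Fourier decomposition and
  no fitting of oscilloscope captures, though digitised captures can be used
  directly as piecewise-linear waveforms.
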