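# Shared builders for synthetic test stacks.

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# A symmetric capacitor-resistor-capacitor stack with an analytically known
# step response: for outer layers with sigma = 0 (series capacitance Cs) and
# a medium with conductance G2 and self-capacitance C2, a voltage step V0
# leaves the medium voltage at
#   v2(t) = V0 * Cs/(Cs + C2) * exp(-G2 * t / (Cs + C2)).
crc_stack <- function(eps_r_cap = 50, sigma_med = 1e-2, radius = 0.01,
                      l_cap = 5e-3, l_med = 5e-3) {
  cap <- material("ideal dielectric", 0, eps_r_cap)
  med <- material("electrolyte", sigma_med, 1)
  stack_setup("crc-test",
              list(layer(cap, l_cap), layer(med, l_med, role = "medium"),
                   layer(cap, l_cap)),
              radius = radius)
}

crc_constants <- function(st) {
  A <- stack_area(st)
  C1 <- layer_capacitance(st$layers[[1]], A)
  C2 <- layer_capacitance(st$layers[[2]], A)
  G2 <- st$layers[[2]]$material$conductivity * A / st$layers[[2]]$thickness
  Cs <- C1 / 2                       # two identical outer capacitors in series
  list(Cs = Cs, C2 = C2, G2 = G2, tau = (Cs + C2) / G2,
       l_med = st$layers[[2]]$thickness)
}

# A small five-layer glass/medium stack, Brighton-like but with round numbers,
# used where a fixture-independent stack is wanted.
demo_stack <- function(waveform = NULL) {
  gls <- material("glass", 1e-13, 7)
  med <- material("medium", 1.5, 80)
  ele <- material("steel", 1e6, 1)
  stack_setup("demo",
              list(layer(ele, 1e-3, role = "electrode"),
                   layer(gls, 0.2e-3), layer(med, 10e-3, role = "medium"),
                   layer(gls, 0.2e-3),
                   layer(ele, 1e-3, role = "electrode")),
              radius = 15e-3, waveform = waveform)
}
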