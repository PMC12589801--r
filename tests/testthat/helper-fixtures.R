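# Shared small fixtures for the suite. Everything is generated in code.

pmma <- pmma_range_table()

# A compact 190 MeV condition for fast pipeline tests.
quick_cond <- function(depth = 5, boron = FALSE, weight = 0, n_events = 2000,
                       seed = 11L, ...) {
  condition_spec(
    beam = preset_beam(190), depth = depth, boron = boron,
    alpha_model = alpha_spectrum_model(weight = weight),
    n_events = n_events, seed = seed, ...
  )
}

# Brute-force slowing-down oracle: energy lost crossing `thickness` um of the
# table material, found by solving R(E_in) - R(E_out) = thickness with a root
# finder that only ever calls interpolate_range (never invert_range).
oracle_energy_loss <- function(e_in, thickness, table) {
  r_in <- interpolate_range(e_in, table)
  stopifnot(r_in > thickness)
  f <- function(e_out) interpolate_range(e_out, table) - (r_in - thickness)
  e_out <- stats::uniroot(f, c(1e-6, e_in), tol = 1e-12)$root
  e_in - e_out
}
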