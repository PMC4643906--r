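# Reference parameter sets and table builders shared across tests.
# The kinetic reference values (Ki = 0.8 uM, alpha = 3.2, substrate span
# 0.5-4 uM, 3 replicates, 5% CV) are the design the synthetic generator
# emulates by default.

ref_mm <- function() mm_params(Km = 1, Vmax = 10)
ref_inhib <- function() inhibition_params(Ki = 0.8, alpha = 3.2)

# Noiseless velocity grid straight from the closed-form model.
exact_mixed_table <- function(S = seq(0.5, 4, length.out = 8),
                              I = c(0, 0.5, 1, 2),
                              p = ref_mm(), q = ref_inhib()) {
  g <- expand.grid(substrate_uM = S, inhibitor_uM = I)
  g$velocity <- mixed_inhibition_velocity(g$substrate_uM, g$inhibitor_uM, p, q)
  g
}

exact_competitive_table <- function(S = seq(0.5, 4, length.out = 8),
                                    I = c(0, 0.5, 1, 2),
                                    p = ref_mm(), Ki = 0.8) {
  g <- expand.grid(substrate_uM = S, inhibitor_uM = I)
  g$velocity <- competitive_velocity(g$substrate_uM, g$inhibitor_uM, p, Ki)
  g
}

# Standard two-inhibitor design: fixed 0.5 uM substrate, primary inhibitor
# bracketing K1 = 0.8 uM, second inhibitor bracketing K2 = 30 uM.
two_inhibitor_config <- function(type = c("exclusive", "synergistic"),
                                 seed = 1, noise_cv = 0.05) {
  type <- match.arg(type)
  mdl <- if (type == "exclusive")
    list(type = "two_inhibitor_exclusive", Km = 1, Vmax = 10, K1 = 0.8, K2 = 30)
  else
    list(type = "two_inhibitor_synergistic", Km = 1, Vmax = 10,
         K1 = 0.8, K2 = 30, beta = 1)
  simulation_config(seed = seed, substrate_grid = 0.5,
                    inhibitor_grid = c(0, 0.25, 0.5, 1, 2),
                    inhibitor2_grid = c(0, 10, 30, 100),
                    model = mdl, noise_cv = noise_cv)
}
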