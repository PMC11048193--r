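# Shared in-code fixtures for the test suite.

identity_A <- function() pfec:::new_instrument_matrix(diag(4))

const_archetype <- function(quv = c(0.5, 0, 0), I = 1, width = 50) {
  species_archetype("const", mean_stokes = c(I, quv),
                    stokes_dispersion = rep(0, 4),
                    shape = list(width_mean = width, width_sd = 0,
                                 asymmetry = 0, flatness = 2),
                    fluorescence_level = 0.5,
                    fluorescence_dispersion = 0)
}

# labeled Stokes traces from a panel, bypassing stream detection
labeled_traces <- function(panel, n_per_class = 100, noise = 0.02,
                           A = default_instrument_matrix(), seed = 1) {
  pulses <- unlist(lapply(seq_along(panel), function(j) {
    lapply(seq_len(n_per_class), function(i)
      simulate_pulse(panel[[j]], A, noise_level = noise,
                     seed = seed + j * 10000 + i))
  }), recursive = FALSE)
  stokes_traces(pulses, A)
}

# two well-separated categories (mean q differs by 0.6)
separable_panel <- function() {
  list(a = species_archetype("a", c(5, 0.5, 0, 0),
                             stokes_dispersion = c(0.2, 0.03, 0.03, 0.03)),
       b = species_archetype("b", c(5, -0.1, 0, 0),
                             stokes_dispersion = c(0.2, 0.03, 0.03, 0.03)))
}

small_mlp <- function(epochs = 60, seed = 7, hidden = c(32, 32)) {
  mlp_config(hidden = hidden, epochs = epochs, seed = seed)
}
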