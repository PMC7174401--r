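# Shared, lazily built fixtures so expensive renders happen once per run.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, duration_s = 0.25, n_particles = 8,
                           noise = TRUE, render = TRUE) {
  key <- paste(name, duration_s, n_particles, noise, render, sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture(
      name, duration_s = duration_s, n_particles = n_particles,
      noise = noise, render = render)
  .fixture_cache[[key]]
}

# Analytic 2D Ornstein-Uhlenbeck MSD: 4 D tau_r (1 - exp(-tau/tau_r))
ou_msd <- function(lag_s, D, tau_r) 4 * D * tau_r * (1 - exp(-lag_s / tau_r))

# Boltzmann constant, J/K
kB <- 1.380649e-23
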