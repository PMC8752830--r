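# Shared fixtures: everything is generated in code, no stored data.

GEOM <- contact_geometry(12.5e-6, 0.5)

# Canonical experiment protocol (50 kHz, 2 um/s, 10 nN trigger).
PROT <- ramp_protocol()

# Desk-scale protocol for unit tests: full 50 kHz sampling (so 1e-4 s arms
# stay resolvable) but a fast ramp and low trigger keep curves ~3k samples.
prot_tiny <- function(noise_sd = 0, trigger_force = 5e-9)
  ramp_protocol(speed = 1e-5, sampling_rate = 5e4,
                trigger_force = trigger_force, noise_sd = noise_sd)

# Scaled benchmark protocol for the heavier acceptance runs: still 50 kHz,
# probe speed and trigger at the fast/low end of the instrument's working
# ranges (2.4 um/s, 5 nN) to halve the curve length.
prot_bench <- function(noise_sd = 0)
  ramp_protocol(speed = 2.4e-6, trigger_force = 5e-9, noise_sd = noise_sd)

cfg_tiny <- function(...) {
  args <- utils::modifyList(list(n_attempts = 8L, seed = 42L), list(...))
  do.call(fit_config, args)
}

sls_100_300 <- function() gm_model(100, G = 300, tau = 1e-3)

max_param_err <- function(fit_model, truth) {
  max(abs(c(fit_model$Ge / truth$Ge, fit_model$G / truth$G,
            fit_model$tau / truth$tau) - 1))
}

# A raw piezo/deflection approach record with a known contact index:
# flat (noisy, tilted) baseline followed by Hertzian contact of a sample
# with shear modulus G_pa. Returns the record written as a CSV plus truth.
make_raw_record <- function(path, n_baseline = 1500L, n_contact = 1500L,
                            rate = 5e3, speed = 2e-6, G_pa = 2000,
                            k = 0.75, noise_m = 0, tilt = 0, seed = 1L,
                            geom = GEOM) {
  n <- n_baseline + n_contact
  t <- seq_len(n) / rate
  z <- speed * t                      # piezo extends at constant speed
  tc <- n_baseline / rate
  k0 <- lr_prefactor(geom)
  d <- numeric(n)
  # in contact: F = k d = k0 G h^1.5 with h = (z - z_c) - d; solve per sample
  for (i in which(t > tc)) {
    zz <- z[i] - z[n_baseline]
    f <- function(dd) k * dd - k0 * G_pa * max(zz - dd, 0)^1.5
    d[i] <- uniroot(f, c(0, zz), tol = 1e-15)$root
  }
  d <- d + tilt * t
  if (noise_m > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    d <- d + rnorm(n, sd = noise_m)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  tab <- data.frame(time_s = t, z_m = z, deflection_m = d)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  list(contact_index = n_baseline, k = k, G = G_pa, rate = rate)
}
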