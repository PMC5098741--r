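# shared fixtures: reference configuration and the standard electroneutral
# soma-subvolume concentration shifts used by the decay scenarios

knp_cfg <- default_configuration()

soma_shifts <- c(Na = -5.1, K = 6.0, Ca = -0.1, X = 0.7)

baseline_named <- stats::setNames(knp_cfg$ions$baseline_concentration,
                                  knp_cfg$ions$name)

# randomized sources in the interior subvolumes whose depth-summed total
# current (ionic + capacitive) is exactly zero at every sample
random_electroneutral_sources <- function(cfg, duration, sample_dt,
                                          amplitude = 1e-9, seed = 1) {
  set.seed(seed)
  ions <- cfg$ions; geometry <- cfg$geometry
  N <- geometry$n_subvolumes
  K <- nrow(ions)
  times <- seq(0, duration, by = sample_dt)
  nt <- length(times)
  Fc <- cfg$constants$faraday
  ion_fluxes <- array(0, c(K, N, nt))
  interior <- 2:(N - 1)
  ion_fluxes[, interior, ] <- stats::rnorm(K * length(interior) * nt,
                                           sd = amplitude / Fc)
  capacitive <- matrix(0, N, nt)
  capacitive[interior, ] <- stats::rnorm(length(interior) * nt,
                                         sd = amplitude)
  for (j in seq_len(nt)) {
    I_M <- as.numeric((Fc * ions$valence) %*%
                        matrix(ion_fluxes[, , j], K, N))
    imbalance <- sum(I_M) + sum(capacitive[, j])
    capacitive[interior, j] <- capacitive[interior, j] -
      imbalance / length(interior)
  }
  source_series(times, ion_fluxes, capacitive, ions, geometry)
}
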