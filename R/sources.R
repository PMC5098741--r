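# Transmembrane source time series: the neuron-side input of the hybrid
# scheme. Either imported from a simulator export (see read_source_series,
# map_segment_currents) or produced by the seeded synthetic population
# generator below.

#' Construct a source time series
#'
#' @param times uniform sample grid in s, starting at 0.
#' @param ion_fluxes array (n_ions x N x n_samples) of per-ion transmembrane
#'   fluxes `J^M` into each subvolume, mol/s. Positive = efflux from neurons
#'   into the ECS.
#' @param capacitive matrix (N x n_samples) of capacitive currents `I^cap`
#'   into each subvolume, A.
#' @param ions,geometry matching configuration objects.
#' @return an object of class `knp_sources`.
#' @export
source_series <- function(times, ion_fluxes, capacitive, ions, geometry) {
  N <- geometry$n_subvolumes
  K <- nrow(ions)
  stopifnot(length(times) >= 1, all(diff(times) > 0))
  dts <- diff(times)
  if (length(dts) && max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("source time grid must be uniform")
  stopifnot(identical(dim(ion_fluxes), c(K, N, length(times))),
            identical(dim(capacitive), c(N, length(times))))
  dimnames(ion_fluxes)[[1]] <- ions$name
  structure(list(times = times,
                 sample_dt = if (length(dts)) dts[1] else Inf,
                 ion_fluxes = ion_fluxes,
                 capacitive = capacitive),
            class = "knp_sources")
}

#' Synthetic population source parameters
#'
#' Parameters of the seeded generator that emulates the statistical structure
#' of a small cortical population's output: Poissonian action-potential (AP)
#' firing, soma-dominated biphasic Na+/K+ current pulses, slow dendritic
#' Ca2+/X- exchange, and a distributed capacitive return current closing each
#' neuron's current loop so the depth-summed total transmembrane current is
#' exactly zero at every instant.
#'
#' @param n_neurons number of neurons (default 10).
#' @param firing_rate mean AP rate per neuron, 1/s (default 5).
#' @param soma_subvolume subvolume receiving the AP Na+/K+ pulses (default 3).
#' @param na_peak,k_peak population-level peak currents of the AP pulses, A
#'   (defaults -30 nA inward Na+, +30 nA outward K+).
#' @param na_tau,k_tau alpha-kernel time constants of the pulses, s.
#' @param k_delay onset delay of the K+ pulse after the Na+ pulse, s.
#' @param dendritic_span subvolume indices carrying dendritic membrane
#'   (return currents and slow fluxes), default 3:14.
#' @param ca_current,x_current slow population-level Ca2+ and X- membrane
#'   currents distributed uniformly over the dendritic span, A (negative =
#'   into the neurons).
#' @param seed RNG seed; identical parameters and seed give bitwise-identical
#'   series.
#' @return a list of class `knp_population_params`.
#' @export
population_params <- function(n_neurons = 10, firing_rate = 5,
                              soma_subvolume = 3,
                              na_peak = -30e-9, k_peak = 30e-9,
                              na_tau = 0.5e-3, k_tau = 1e-3,
                              k_delay = 1e-3,
                              dendritic_span = 3:14,
                              ca_current = -0.5e-9, x_current = 1e-9,
                              seed = 1) {
  stopifnot(n_neurons >= 1, firing_rate >= 0,
            all(is.finite(c(na_peak, k_peak, ca_current, x_current))),
            na_tau > 0, k_tau > 0, k_delay >= 0)
  structure(list(n_neurons = as.integer(n_neurons),
                 firing_rate = firing_rate,
                 soma_subvolume = as.integer(soma_subvolume),
                 na_peak = na_peak, k_peak = k_peak,
                 na_tau = na_tau, k_tau = k_tau, k_delay = k_delay,
                 dendritic_span = as.integer(dendritic_span),
                 ca_current = ca_current, x_current = x_current,
                 seed = as.integer(seed)),
            class = "knp_population_params")
}

# alpha kernel, unit peak at t = tau
alpha_kernel <- function(t, tau) {
  k <- t / tau * exp(1 - t / tau)
  k[t < 0] <- 0
  k
}

#' Generate synthetic population sources
#'
#' For each neuron an independent Poisson AP train at `firing_rate`; each AP
#' deposits a biphasic pair of alpha-shaped current pulses into the soma
#' subvolume (Na+ influx into the cell, then delayed K+ efflux). Slow Ca2+
#' and X- currents are spread uniformly over the dendritic span. At every
#' sample the total ionic membrane current is balanced by a capacitive
#' current distributed over the dendritic span, so the depth-summed total
#' transmembrane current is exactly zero — the conservation property the
#' Kirchhoff potential solve requires of its input.
#'
#' @param params a `knp_population_params` object.
#' @param duration total covered time, s.
#' @param sample_dt sample interval, s (default 0.1 ms, resolving AP pulses).
#' @param ions,geometry matching configuration objects.
#' @return a `knp_sources` object.
#' @export
generate_population_sources <- function(params = population_params(),
                                        duration, sample_dt = 1e-4,
                                        ions = default_ion_set(),
                                        geometry = ecs_geometry()) {
  stopifnot(inherits(params, "knp_population_params"),
            duration > 0, sample_dt > 0)
  N <- geometry$n_subvolumes
  K <- nrow(ions)
  stopifnot(params$soma_subvolume > 1, params$soma_subvolume < N,
            all(params$dendritic_span > 1), all(params$dendritic_span < N))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(params$seed)

  times <- seq(0, duration, by = sample_dt)
  nt <- length(times)
  iK <- match("K", ions$name); iNa <- match("Na", ions$name)
  iCa <- match("Ca", ions$name); iX <- match("X", ions$name)
  Fc <- 96485

  # per-neuron pulse amplitudes (A)
  na_amp <- params$na_peak / params$n_neurons
  k_amp <- params$k_peak / params$n_neurons
  # soma AP current traces (population sums)
  I_na <- numeric(nt); I_k <- numeric(nt)
  kern_len <- ceiling(8 * max(params$na_tau, params$k_tau) / sample_dt)
  ap_times_by_neuron <- vector("list", params$n_neurons)
  for (neuron in seq_len(params$n_neurons)) {
    n_ap <- stats::rpois(1, params$firing_rate * duration)
    ap_times <- sort(stats::runif(n_ap, 0, duration))
    ap_times_by_neuron[[neuron]] <- ap_times
    for (t0 in ap_times) {
      j0 <- floor(t0 / sample_dt) + 1
      jj <- j0:min(j0 + kern_len, nt)
      tt <- times[jj] - t0
      I_na[jj] <- I_na[jj] + na_amp * alpha_kernel(tt, params$na_tau)
      I_k[jj] <- I_k[jj] + k_amp * alpha_kernel(tt - params$k_delay,
                                                params$k_tau)
    }
  }

  dend <- params$dendritic_span
  w <- rep(1 / length(dend), length(dend))

  ion_fluxes <- array(0, c(K, N, nt))
  if (!is.na(iNa)) ion_fluxes[iNa, params$soma_subvolume, ] <- I_na / Fc
  if (!is.na(iK)) ion_fluxes[iK, params$soma_subvolume, ] <- I_k / Fc
  if (!is.na(iCa))
    ion_fluxes[iCa, dend, ] <- outer(w * params$ca_current / (2 * Fc),
                                     rep(1, nt))
  if (!is.na(iX))
    ion_fluxes[iX, dend, ] <- outer(-w * params$x_current / Fc, rep(1, nt))

  # capacitive closure: cancel the depth-summed ionic current at each sample
  I_M <- apply(ion_fluxes, 3, function(J)
    as.numeric((Fc * ions$valence) %*% J))      # N x nt
  I_M <- matrix(I_M, N, nt)
  total_ionic <- colSums(I_M)
  capacitive <- matrix(0, N, nt)
  capacitive[dend, ] <- -outer(w, total_ionic)

  out <- source_series(times, ion_fluxes, capacitive, ions, geometry)
  attr(out, "ap_times") <- ap_times_by_neuron
  out
}

#' Validate a source series
#'
#' Checks that (i) the edge subvolumes carry no sources, (ii) the
#' depth-summed total transmembrane current (ionic + capacitive) vanishes at
#' every sample within `tolerance`, and (iii) all values are finite. Returns
#' a report rather than raising.
#'
#' @param series a `knp_sources` object.
#' @param ions matching ion table.
#' @param tolerance current-imbalance tolerance in A (default 1e-12).
#' @return list with `pass` (logical), `worst_imbalance` (A),
#'   `worst_sample` (index), and a character vector `failures`.
#' @export
validate_sources <- function(series, ions, tolerance = 1e-12) {
  stopifnot(inherits(series, "knp_sources"))
  N <- dim(series$capacitive)[1]
  nt <- length(series$times)
  failures <- character(0)
  if (!all(is.finite(series$ion_fluxes)) || !all(is.finite(series$capacitive)))
    failures <- c(failures, "non-finite values present")
  edge <- c(1L, N)
  if (any(series$ion_fluxes[, edge, ] != 0) ||
      any(series$capacitive[edge, ] != 0))
    failures <- c(failures, "edge subvolumes carry nonzero sources")
  Fc <- 96485
  imbalance <- vapply(seq_len(nt), function(j) {
    I_M <- as.numeric((Fc * ions$valence) %*%
                        matrix(series$ion_fluxes[, , j], nrow(ions), N))
    sum(I_M) + sum(series$capacitive[, j])
  }, numeric(1))
  worst <- which.max(abs(imbalance))
  if (abs(imbalance[worst]) > tolerance)
    failures <- c(failures, sprintf(
      "depth-summed current imbalance %.3g A at sample %d exceeds tolerance",
      imbalance[worst], worst))
  list(pass = length(failures) == 0,
       worst_imbalance = imbalance[worst],
       worst_sample = worst,
       failures = failures)
}

#' Map per-segment membrane current densities to subvolume sources
#'
#' Converts a table of per-segment channel current densities, as exported
#' from a compartmental neuron simulator, into a single-sample source
#' series. Each channel is assigned to a carrier ion (or to the capacitive
#' current) via `channel_map`; currents are converted to fluxes with the
#' carrier's valence: `J^k_n = (1/(z_k F)) sum_seg i_seg A_seg` (so Ca2+
#' currents are divided by 2F and X- currents change sign).
#'
#' @param table data.frame with columns `segment`, `subvolume`, `area`
#'   (m^2), `channel`, `density` (A/m^2).
#' @param channel_map named character vector mapping each channel label to an
#'   ion name in `ions`, or to `"cap"` for capacitive current.
#' @param ions,geometry matching configuration objects.
#' @return a single-sample `knp_sources` object (time 0).
#' @export
map_segment_currents <- function(table, channel_map, ions, geometry) {
  N <- geometry$n_subvolumes
  K <- nrow(ions)
  needed <- c("segment", "subvolume", "area", "channel", "density")
  if (!all(needed %in% names(table)))
    stop("table must have columns ", paste(needed, collapse = ", "))
  if (nrow(table)) {
    if (any(table$area <= 0)) stop("segment areas must be positive")
    if (any(table$subvolume < 2 | table$subvolume > N - 1))
      stop("segment subvolume indices must be interior (2..N-1)")
    unknown <- setdiff(unique(table$channel), names(channel_map))
    if (length(unknown))
      stop("channels without an ion mapping: ",
           paste(unknown, collapse = ", "))
    bad <- setdiff(setdiff(unique(channel_map), "cap"), ions$name)
    if (length(bad))
      stop("channel_map targets unknown ions: ", paste(bad, collapse = ", "))
  }
  Fc <- 96485
  ion_fluxes <- array(0, c(K, N, 1))
  capacitive <- matrix(0, N, 1)
  if (nrow(table)) {
    target <- channel_map[table$channel]
    current <- table$density * table$area
    for (r in seq_len(nrow(table))) {
      n <- table$subvolume[r]
      if (target[r] == "cap") {
        capacitive[n, 1] <- capacitive[n, 1] + current[r]
      } else {
        k <- match(target[r], ions$name)
        ion_fluxes[k, n, 1] <- ion_fluxes[k, n, 1] +
          current[r] / (ions$valence[k] * Fc)
      }
    }
  }
  source_series(0, ion_fluxes, capacitive, ions, geometry)
}

#' @export
print.knp_sources <- function(x, ...) {
  cat("KNP source series:", length(x$times), "samples, dt =",
      format(x$sample_dt), "s\n")
  cat("  ions:", paste(dimnames(x$ion_fluxes)[[1]], collapse = ", "), "\n")
  invisible(x)
}
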