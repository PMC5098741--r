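# Analysis operators: time-averaged depth profiles, log-binned power
# spectra, power-law fits, liquid-junction potential calculators, and
# current-source-density estimation with and without the diffusion
# correction.

#' Time-averaged depth profiles from a trajectory
#'
#' Arithmetic mean of a recorded quantity per subvolume (or interface) over
#' one or more time intervals — the discrete low-pass used to display slow
#' depth structure.
#'
#' @param trajectory a `knp_trajectory`.
#' @param quantity one of `"potential"`, `"concentration"`,
#'   `"diffusive_current"`, `"field_current"`.
#' @param intervals list of `c(t0, t1)` pairs (s), each within the recorded
#'   span and containing at least one sample.
#' @param ion ion name, required when `quantity = "concentration"`.
#' @return matrix with one column per interval (rows: subvolumes, or
#'   interfaces for currents); attribute `"intervals"` carries the request.
#' @export
time_average_profile <- function(trajectory,
                                 quantity = c("potential", "concentration",
                                              "diffusive_current",
                                              "field_current"),
                                 intervals, ion = NULL) {
  quantity <- match.arg(quantity)
  if (is.numeric(intervals) && length(intervals) == 2)
    intervals <- list(intervals)
  if (quantity == "concentration") {
    if (is.null(ion)) stop("ion must be given for concentration profiles")
    tt <- trajectory$conc_times
    M <- trajectory$concentrations[ion, , , drop = TRUE]
    M <- matrix(M, dim(trajectory$concentrations)[2], length(tt))
  } else {
    tt <- trajectory$times
    M <- trajectory[[quantity]]
  }
  out <- vapply(intervals, function(iv) {
    sel <- tt >= iv[1] & tt <= iv[2]
    if (!any(sel)) stop("interval [", iv[1], ", ", iv[2],
                        "] contains no recorded samples")
    rowMeans(M[, sel, drop = FALSE])
  }, numeric(nrow(M)))
  out <- matrix(out, nrow(M), length(intervals))
  attr(out, "intervals") <- intervals
  out
}

#' Log-binned power spectral density
#'
#' One-sided periodogram of the mean-subtracted signal (FFT-based), then
#' smoothed by averaging into geometric frequency bins of `log_bin` decades.
#' The raw periodogram satisfies Parseval: `sum(raw_power) * df` equals the
#' signal variance (up to the mean-removal correction).
#'
#' @param signal uniformly sampled time series (length >= 16).
#' @param sample_dt sample interval in s.
#' @param log_bin bin width in decades of frequency (default 0.1).
#' @param window `"none"` (default: mean subtraction only) or `"hann"`.
#' @return an object of class `knp_spectrum`: `frequencies` (Hz, bin
#'   geometric means), `power` (signal^2/Hz), `bin_decades`, plus the
#'   unbinned `raw_frequencies`/`raw_power` and `variance` of the input.
#' @export
power_spectrum <- function(signal, sample_dt, log_bin = 0.1,
                           window = c("none", "hann")) {
  window <- match.arg(window)
  n <- length(signal)
  if (n < 16) stop("signal too short for a spectrum (need >= 16 samples)")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  x <- signal - mean(signal)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w / sqrt(mean(w^2))
  }
  X <- stats::fft(x)
  nfreq <- floor(n / 2)
  freq <- seq_len(nfreq) / (n * sample_dt)
  power <- 2 * sample_dt / n * Mod(X[2:(nfreq + 1)])^2
  if (n %% 2 == 0) power[nfreq] <- power[nfreq] / 2  # Nyquist is unpaired

  edges <- 10^seq(floor(log10(freq[1]) / log_bin) * log_bin,
                  ceiling(log10(freq[nfreq]) / log_bin) * log_bin,
                  by = log_bin)
  bin <- findInterval(freq, edges, rightmost.closed = TRUE)
  keep <- bin >= 1
  bfreq <- exp(tapply(log(freq[keep]), bin[keep], mean))
  bpow <- tapply(power[keep], bin[keep], mean)
  structure(list(frequencies = as.numeric(bfreq),
                 power = as.numeric(bpow),
                 bin_decades = log_bin,
                 raw_frequencies = freq,
                 raw_power = power,
                 variance = stats::var(x)),
            class = "knp_spectrum")
}

#' Least-squares power-law fit of a spectrum
#'
#' Fits a straight line to `log10(power)` vs `log10(frequency)` over a band
#' and reports the exponent as the positive magnitude `beta` of `1/f^beta`.
#'
#' @param spectrum a `knp_spectrum`.
#' @param band `c(f_lo, f_hi)` in Hz; at least 4 binned points must fall
#'   inside.
#' @return list of class `knp_powerlaw`: `exponent` (magnitude),
#'   `amplitude` (power at 1 Hz), `band`, `r_squared`, `n_points`.
#' @export
fit_power_law <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "knp_spectrum"), length(band) == 2)
  sel <- spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2] &
    spectrum$power > 0
  if (sum(sel) < 4)
    stop("fewer than 4 spectral bins in the fit band")
  lf <- log10(spectrum$frequencies[sel])
  lp <- log10(spectrum$power[sel])
  fit <- stats::lm(lp ~ lf)
  ss_tot <- sum((lp - mean(lp))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(exponent = -unname(stats::coef(fit)[2]),
                 amplitude = 10^unname(stats::coef(fit)[1]),
                 band = band,
                 r_squared = r2,
                 n_points = sum(sel)),
            class = "knp_powerlaw")
}

# resolve a per-ion concentration argument into a vector in ion-set order
resolve_conc <- function(conc, ions) {
  if (!is.null(names(conc))) {
    missing <- setdiff(ions$name, names(conc))
    if (length(missing))
      stop("missing concentrations for: ", paste(missing, collapse = ", "))
    conc <- conc[ions$name]
  }
  stopifnot(length(conc) == nrow(ions))
  as.numeric(conc)
}

#' Goldman-Hodgkin-Katz potential between two compartments
#'
#' Zero-net-current (equilibrium) potential `V_B - V_A` between two
#' electrolyte compositions, from the GHK voltage equation over the
#' monovalent species, with the effective diffusion constants playing the
#' role of permeabilities (the tortuosity factor cancels in the ratio).
#' Divalent species are excluded — the standard GHK voltage equation is a
#' monovalent result, and Ca2+ at its trace ECS concentration contributes
#' negligibly. Use [henderson_potential()] for arbitrary valences.
#'
#' @param conc_a,conc_b per-ion concentration vectors (mol/m^3), named by
#'   ion or in ion-set order. All monovalent entries must be positive.
#' @param ions,constants matching configuration objects.
#' @return potential `V_B - V_A` in V.
#' @examples
#' cfg <- default_configuration()
#' base <- stats::setNames(cfg$ions$baseline_concentration, cfg$ions$name)
#' shifted <- base + c(K = 6, Na = -5.1, Ca = -0.1, X = 0.7)[cfg$ions$name]
#' ghk_potential(base, shifted, cfg$ions, cfg$constants) * 1e3  # ~ -0.18 mV
#' @export
ghk_potential <- function(conc_a, conc_b, ions, constants) {
  ca <- resolve_conc(conc_a, ions)
  cb <- resolve_conc(conc_b, ions)
  mono <- abs(ions$valence) == 1
  if (!any(mono)) stop("no monovalent species in the ion set")
  if (any(ca[mono] <= 0) || any(cb[mono] <= 0))
    stop("all monovalent concentrations must be positive")
  D <- ions$diffusion_constant
  cat_ <- mono & ions$valence == 1
  an_ <- mono & ions$valence == -1
  num <- sum(D[cat_] * ca[cat_]) + sum(D[an_] * cb[an_])
  den <- sum(D[cat_] * cb[cat_]) + sum(D[an_] * ca[an_])
  if (den <= 0) stop("degenerate GHK denominator")
  constants$psi * log(num / den)
}

#' Henderson liquid-junction potential
#'
#' Classical Henderson formula for the junction potential `V_B - V_A`
#' between two electrolyte compositions, assuming a linear mixing profile
#' across the junction. With mobilities proportional to `|z| D`, it reads
#' `V = -psi * W * ln(S_B/S_A) / (S_B - S_A)` where `W = sum z D (c_B - c_A)`
#' and `S = sum z^2 D c`. Supports arbitrary valences; tortuosity cancels.
#'
#' @inheritParams ghk_potential
#' @return potential `V_B - V_A` in V.
#' @export
henderson_potential <- function(conc_a, conc_b, ions, constants) {
  ca <- resolve_conc(conc_a, ions)
  cb <- resolve_conc(conc_b, ions)
  if (any(ca < 0) || any(cb < 0)) stop("concentrations must be non-negative")
  D <- ions$diffusion_constant
  z <- ions$valence
  S_a <- sum(z^2 * D * ca)
  S_b <- sum(z^2 * D * cb)
  if (S_a <= 0 || S_b <= 0)
    stop("degenerate junction: zero mobility-weighted concentration")
  W <- sum(z * D * (cb - ca))
  if (abs(S_b - S_a) < 1e-12 * S_a)
    return(-constants$psi * W / S_a)
  -constants$psi * W * log(S_b / S_a) / (S_b - S_a)
}

#' Standard current-source density estimate
#'
#' The classical CSD estimator `-grad(sigma grad V) = CSD`, discretized as
#' centered second differences over the subvolume grid. It attributes *all*
#' spatial structure of the potential to transmembrane sources, which
#' misreads diffusive ECS currents as neuronal sources when concentration
#' gradients are present; see [csd_diffusion_corrected()].
#'
#' @param v_profile per-subvolume potential, V (length N).
#' @param sigma per-interface conductivities, S/m (length N-1).
#' @param geometry a `knp_geometry`.
#' @return per-subvolume CSD in A per m^3 of ECS; the edge (reservoir)
#'   subvolumes are `NA`.
#' @export
csd_standard <- function(v_profile, sigma, geometry) {
  N <- geometry$n_subvolumes
  stopifnot(length(v_profile) == N, length(sigma) == N - 1)
  lc <- geometry$subvolume_height
  phi <- sigma * diff(v_profile)            # sigma * dV at each interface
  csd <- rep(NA_real_, N)
  csd[2:(N - 1)] <- -(phi[2:(N - 1)] - phi[1:(N - 2)]) / lc^2
  csd
}

#' Diffusion-corrected current-source density estimate
#'
#' As [csd_standard()], but first removes the divergence of the diffusive
#' current density from the potential's second difference:
#' `grad(sigma grad V) - grad(i_d) = -CSD`. On a potential/concentration
#' snapshot from an electrodiffusive simulation this recovers the true
#' transmembrane source density, and reports (numerically) zero where the
#' standard estimator reports spurious sources generated by diffusion.
#'
#' @param v_profile per-subvolume potential, V (length N).
#' @param conc_profiles per-ion, per-subvolume concentration matrix
#'   (n_ions x N, mol/m^3); also used to evaluate the interface
#'   conductivities.
#' @param ions,geometry,constants matching configuration objects.
#' @return per-subvolume CSD in A per m^3 of ECS; edges `NA`.
#' @export
csd_diffusion_corrected <- function(v_profile, conc_profiles, ions,
                                    geometry, constants) {
  N <- geometry$n_subvolumes
  conc_profiles <- as.matrix(conc_profiles)
  stopifnot(nrow(conc_profiles) == nrow(ions), ncol(conc_profiles) == N)
  sigma <- interface_conductivity(conc_profiles[, -N, drop = FALSE],
                                  conc_profiles[, -1, drop = FALSE],
                                  ions, constants, geometry)
  lc <- geometry$subvolume_height
  Deff <- effective_diffusion(ions, geometry)
  dc <- conc_profiles[, -1, drop = FALSE] - conc_profiles[, -N, drop = FALSE]
  # diffusive current density per unit ECS area at each interface
  i_d <- -constants$faraday / lc *
    as.numeric((ions$valence * Deff) %*% dc)
  csd <- csd_standard(v_profile, sigma, geometry)
  csd[2:(N - 1)] <- csd[2:(N - 1)] +
    (i_d[2:(N - 1)] - i_d[1:(N - 2)]) / lc
  csd
}

#' @export
print.knp_powerlaw <- function(x, ...) {
  cat(sprintf("power-law fit: 1/f^%.3f over [%g, %g] Hz (R^2 = %.4f, %d bins)\n",
              x$exponent, x$band[1], x$band[2], x$r_squared, x$n_points))
  invisible(x)
}

#' @export
print.knp_spectrum <- function(x, ...) {
  cat("log-binned power spectrum:", length(x$frequencies), "bins of",
      x$bin_decades, "decades, ",
      format(min(x$frequencies), digits = 3), "-",
      format(max(x$frequencies), digits = 3), "Hz\n")
  invisible(x)
}
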