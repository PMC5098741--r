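#' Physical constants
#'
#' Faraday's constant, the gas constant and the absolute temperature, together
#' with the derived thermal voltage `psi = R*T/F` used throughout the
#' Nernst-Planck flux and conductivity expressions. `psi` is always recomputed
#' from `temperature`, never stored independently.
#'
#' @param temperature absolute temperature in K. Default 300 K.
#' @return an object of class `knp_constants`: a list with elements
#'   `faraday` (C/mol), `gas_constant` (J/(mol K)), `temperature` (K) and
#'   `psi` (V).
#' @examples
#' physical_constants()$psi   # ~25.9 mV at 300 K
#' @export
physical_constants <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  F_const <- 96485
  R_const <- 8.314
  structure(list(
    faraday      = F_const,
    gas_constant = R_const,
    temperature  = temperature,
    psi          = R_const * temperature / F_const
  ), class = "knp_constants")
}

#' Define a set of ionic species
#'
#' An ion set is the parameter table behind every flux and conductivity
#' formula: one row per species with its valence, free-solution diffusion
#' constant and baseline (reservoir) concentration. Concentrations are in
#' mol/m^3, numerically equal to mM.
#'
#' @param name character vector of unique species labels.
#' @param valence integer-valued vector of signed valences (nonzero).
#' @param diffusion_constant free-solution diffusion coefficients in m^2/s
#'   (tortuosity is applied separately as `D/lambda^2`).
#' @param baseline_concentration baseline concentrations in mol/m^3 (>= 0).
#' @return a `data.frame` of class `knp_ions`.
#' @seealso [default_ion_set()], [electroneutral_anion_concentration()]
#' @export
ion_set <- function(name, valence, diffusion_constant, baseline_concentration) {
  stopifnot(length(name) == length(valence),
            length(name) == length(diffusion_constant),
            length(name) == length(baseline_concentration))
  if (anyDuplicated(name))
    stop("ion names must be unique")
  if (any(valence == 0) || any(valence != round(valence)))
    stop("valences must be nonzero integers")
  if (any(diffusion_constant <= 0))
    stop("diffusion constants must be positive")
  if (any(baseline_concentration < 0))
    stop("baseline concentrations must be non-negative")
  structure(
    data.frame(name = as.character(name),
               valence = as.integer(valence),
               diffusion_constant = as.numeric(diffusion_constant),
               baseline_concentration = as.numeric(baseline_concentration),
               stringsAsFactors = FALSE),
    class = c("knp_ions", "data.frame"))
}

#' Default ion set: K+, Na+, Ca2+ and the unspecified anion X-
#'
#' X- stands in for all unspecified anionic charge carriers (essentially Cl-
#' in real tissue: it carries the Cl- diffusion constant) and its baseline of
#' 155.8 mol/m^3 makes the set exactly charge-neutral at baseline.
#'
#' @return a `knp_ions` table with rows K, Na, Ca, X.
#' @export
default_ion_set <- function() {
  ion_set(name = c("K", "Na", "Ca", "X"),
          valence = c(1L, 1L, 2L, -1L),
          diffusion_constant = c(1.96e-9, 1.33e-9, 0.71e-9, 2.03e-9),
          baseline_concentration = c(3, 150, 1.4, 155.8))
}

#' Discretized 1D extracellular column
#'
#' The tissue column is split into `n_subvolumes` boxes of height
#' `subvolume_height` stacked along depth. `cross_section` is the *tissue*
#' cross-section; only the fraction `volume_fraction` (alpha) of it is
#' extracellular, so every transport formula uses the ECS cross-section
#' `alpha * A_c`. `tortuosity` (lambda) reduces effective diffusion to
#' `D/lambda^2`. The two edge boxes act as constant-concentration reservoirs.
#'
#' @param n_subvolumes integer N >= 3 (two reservoir edges plus interior).
#' @param subvolume_height box height l_c in m.
#' @param cross_section tissue cross-section A_c in m^2.
#' @param volume_fraction ECS volume fraction alpha, in (0, 1].
#' @param tortuosity tortuosity lambda >= 1.
#' @return an object of class `knp_geometry`.
#' @export
ecs_geometry <- function(n_subvolumes = 15, subvolume_height = 100e-6,
                         cross_section = 3000e-12, volume_fraction = 0.2,
                         tortuosity = 1.6) {
  stopifnot(n_subvolumes == round(n_subvolumes), n_subvolumes >= 3,
            subvolume_height > 0, cross_section > 0,
            volume_fraction > 0, volume_fraction <= 1,
            tortuosity >= 1)
  structure(list(
    n_subvolumes     = as.integer(n_subvolumes),
    subvolume_height = subvolume_height,
    cross_section    = cross_section,
    volume_fraction  = volume_fraction,
    tortuosity       = tortuosity
  ), class = "knp_geometry")
}

#' Reference configuration of the simulator
#'
#' Returns the standard cortical-column configuration: a 15-box column of
#' 100 um boxes over a 3000 um^2 tissue cross-section with alpha = 0.2 (ECS
#' cross-section 600 um^2) and lambda = 1.6, the four-species ion set of
#' [default_ion_set()], and constants at 300 K.
#'
#' @param temperature absolute temperature in K passed to
#'   [physical_constants()].
#' @return a list with elements `ions`, `geometry`, `constants`.
#' @examples
#' cfg <- default_configuration()
#' with(cfg$geometry, volume_fraction * cross_section)  # 600 um^2 in m^2
#' @export
default_configuration <- function(temperature = 300) {
  list(ions = default_ion_set(),
       geometry = ecs_geometry(),
       constants = physical_constants(temperature))
}

#' Baseline concentration of a neutralizing monovalent anion
#'
#' Given the cations (and any other species) of an ion set, returns the
#' concentration at which a monovalent anion must be added so that the
#' baseline charge density `F * sum(z * c0)` is exactly zero.
#'
#' @param ions a `knp_ions` table *without* the anion to be determined.
#' @return the required anion concentration in mol/m^3.
#' @examples
#' ions <- ion_set(c("K", "Na", "Ca"), c(1, 1, 2),
#'                 c(1.96e-9, 1.33e-9, 0.71e-9), c(3, 150, 1.4))
#' electroneutral_anion_concentration(ions)  # 155.8
#' @export
electroneutral_anion_concentration <- function(ions) {
  stopifnot(inherits(ions, "knp_ions"))
  net <- sum(ions$valence * ions$baseline_concentration)
  if (net <= 0)
    stop("remaining net baseline charge is not positive; ",
         "a monovalent anion cannot neutralize it")
  net
}

#' ECS state at one instant
#'
#' Bundles the per-ion, per-subvolume concentration matrix and the
#' per-subvolume potential at a given time. Rows of `concentrations` follow
#' the ion-set order and are named accordingly.
#'
#' @param concentrations numeric matrix, one row per ion, one column per
#'   subvolume, in mol/m^3; all entries >= 0.
#' @param potential numeric vector of length N, in V (defaults to all zero).
#' @param time time stamp in s.
#' @param ions the `knp_ions` table the rows refer to.
#' @param geometry the `knp_geometry` the columns refer to.
#' @return an object of class `knp_state`.
#' @export
ecs_state <- function(concentrations, potential = NULL, time = 0,
                      ions, geometry) {
  stopifnot(inherits(ions, "knp_ions"), inherits(geometry, "knp_geometry"))
  N <- geometry$n_subvolumes
  concentrations <- as.matrix(concentrations)
  if (nrow(concentrations) != nrow(ions) || ncol(concentrations) != N)
    stop("concentration matrix must be n_ions x n_subvolumes")
  if (any(concentrations < 0))
    stop("concentrations must be non-negative")
  if (is.null(potential)) potential <- rep(0, N)
  stopifnot(length(potential) == N)
  rownames(concentrations) <- ions$name
  structure(list(concentrations = concentrations,
                 potential = as.numeric(potential),
                 time = time),
            class = "knp_state")
}

#' Baseline (resting) ECS state
#'
#' All subvolumes at the ion set's baseline concentrations, potential zero.
#'
#' @inheritParams ecs_state
#' @return a `knp_state`.
#' @export
baseline_state <- function(ions, geometry) {
  conc <- matrix(ions$baseline_concentration,
                 nrow = nrow(ions), ncol = geometry$n_subvolumes)
  ecs_state(conc, time = 0, ions = ions, geometry = geometry)
}

#' Baseline state with concentration shifts in one subvolume
#'
#' Convenience constructor for localized-perturbation scenarios: all
#' subvolumes at baseline except `subvolume`, whose concentrations are
#' shifted by `shifts` (mol/m^3, named by ion; unnamed ions unshifted).
#'
#' @param config list with `ions`, `geometry`, `constants`.
#' @param subvolume interior subvolume index to perturb.
#' @param shifts named numeric vector of concentration shifts in mol/m^3.
#' @return a `knp_state`.
#' @examples
#' st <- perturbed_state(default_configuration(), 3,
#'                       c(Na = -5.1, K = 6.0, Ca = -0.1, X = 0.7))
#' @export
perturbed_state <- function(config, subvolume, shifts) {
  ions <- config$ions; geometry <- config$geometry
  N <- geometry$n_subvolumes
  stopifnot(subvolume > 1, subvolume < N)
  unknown <- setdiff(names(shifts), ions$name)
  if (length(unknown))
    stop("shifts name unknown ions: ", paste(unknown, collapse = ", "))
  state <- baseline_state(ions, geometry)
  k <- match(names(shifts), ions$name)
  state$concentrations[k, subvolume] <-
    state$concentrations[k, subvolume] + shifts
  if (any(state$concentrations < 0))
    stop("shifts drive a concentration negative")
  state
}

#' Per-subvolume charge density
#'
#' `rho_n = F * sum_k z_k * c_nk`, the net free charge per unit ECS volume.
#' Zero everywhere for any electroneutral state.
#'
#' @param state a `knp_state`.
#' @param ions the matching `knp_ions` table.
#' @param constants a `knp_constants` object.
#' @return numeric vector of length N, in C/m^3.
#' @export
charge_density <- function(state, ions, constants = physical_constants()) {
  stopifnot(inherits(state, "knp_state"), inherits(ions, "knp_ions"))
  if (nrow(state$concentrations) != nrow(ions) ||
      !identical(rownames(state$concentrations), ions$name))
    stop("state and ion set do not match")
  as.numeric(constants$faraday * (ions$valence %*% state$concentrations))
}

#' @export
print.knp_state <- function(x, ...) {
  cat("KNP ECS state at t =", format(x$time), "s\n")
  cat("  subvolumes:", ncol(x$concentrations),
      " ions:", paste(rownames(x$concentrations), collapse = ", "), "\n")
  cat("  potential range [V]:",
      format(range(x$potential), digits = 4), "\n")
  invisible(x)
}

#' @export
print.knp_geometry <- function(x, ...) {
  cat("KNP column geometry: N =", x$n_subvolumes,
      "boxes of", x$subvolume_height * 1e6, "um\n")
  cat("  tissue cross-section:", x$cross_section * 1e12, "um^2,",
      "alpha =", x$volume_fraction, ", lambda =", x$tortuosity, "\n")
  invisible(x)
}
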