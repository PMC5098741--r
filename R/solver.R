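# Nernst-Planck fluxes, Kirchhoff potential solve and explicit time stepping.
# All quantities strict SI: m, s, V, A, mol/m^3, S/m. Interface i sits between
# subvolumes i and i+1 (i = 1..N-1); positive flux/current points toward
# larger subvolume index (deeper).

# effective (tortuosity-corrected) diffusion constants D/lambda^2
effective_diffusion <- function(ions, geometry) {
  ions$diffusion_constant / geometry$tortuosity^2
}

#' Electrical conductivity of the electrolyte between two subvolumes
#'
#' `sigma = (F/psi) * sum_k D_k z_k^2 / lambda^2 * (c_left + c_right)/2`,
#' the concentration-dependent bulk conductivity of the ECS electrolyte,
#' evaluated with the arithmetic mean of the two neighboring concentrations.
#'
#' @param c_left,c_right per-ion concentration vectors (mol/m^3), in ion-set
#'   order. Matrices with one column per interface are accepted, giving a
#'   vector of conductivities.
#' @param ions a `knp_ions` table.
#' @param constants a `knp_constants` object.
#' @param geometry a `knp_geometry` object (supplies the tortuosity).
#' @return conductivity in S/m (scalar, or one value per column).
#' @examples
#' cfg <- default_configuration()
#' c0 <- cfg$ions$baseline_concentration
#' interface_conductivity(c0, c0, cfg$ions, cfg$constants, cfg$geometry)
#' @export
interface_conductivity <- function(c_left, c_right, ions, constants, geometry) {
  c_left <- as.matrix(c_left); c_right <- as.matrix(c_right)
  if (any(c_left < 0) || any(c_right < 0))
    stop("concentrations must be non-negative")
  w <- constants$faraday / constants$psi *
    effective_diffusion(ions, geometry) * ions$valence^2
  as.numeric(w %*% ((c_left + c_right) / 2))
}

# conductivity at every interface of a state: vector of length N-1
interface_conductivities <- function(state, ions, constants, geometry) {
  N <- geometry$n_subvolumes
  interface_conductivity(state$concentrations[, -N, drop = FALSE],
                         state$concentrations[, -1, drop = FALSE],
                         ions, constants, geometry)
}

#' Apparent (tissue-referenced) conductivity
#'
#' Experimental work often references ECS currents to the whole tissue volume
#' rather than the ECS fraction; the apparent conductivity is then
#' `sigma' = alpha * sigma`.
#'
#' @param sigma ECS conductivity in S/m (>= 0).
#' @param geometry a `knp_geometry` (supplies alpha).
#' @return apparent conductivity in S/m.
#' @export
apparent_conductivity <- function(sigma, geometry) {
  stopifnot(all(sigma >= 0))
  geometry$volume_fraction * sigma
}

#' Diffusive fluxes across every interface
#'
#' Fickian flux through the porous ECS:
#' `J^d_{n,n+1} = -(alpha A_c / l_c) (D_k/lambda^2) (c_{n+1} - c_n)`.
#' Positive values point toward larger subvolume index.
#'
#' @param state a `knp_state`.
#' @param ions,geometry matching configuration objects.
#' @return matrix (n_ions x N-1) of fluxes in mol/s.
#' @export
diffusive_fluxes <- function(state, ions, geometry) {
  N <- geometry$n_subvolumes
  g <- geometry$volume_fraction * geometry$cross_section /
    geometry$subvolume_height
  dc <- state$concentrations[, -1, drop = FALSE] -
    state$concentrations[, -N, drop = FALSE]
  -g * effective_diffusion(ions, geometry) * dc
}

#' Field (drift) fluxes across every interface
#'
#' Electromigration driven by the potential gradient:
#' `J^f_{n,n+1} = -(alpha A_c / (psi l_c)) z_k (D_k/lambda^2)
#'   ((c_n + c_{n+1})/2) (V_{n+1} - V_n)`.
#'
#' @param state a `knp_state` whose `potential` has been solved.
#' @param ions,constants,geometry matching configuration objects.
#' @return matrix (n_ions x N-1) of fluxes in mol/s.
#' @export
field_fluxes <- function(state, ions, constants, geometry) {
  N <- geometry$n_subvolumes
  g <- geometry$volume_fraction * geometry$cross_section /
    (constants$psi * geometry$subvolume_height)
  cbar <- (state$concentrations[, -1, drop = FALSE] +
             state$concentrations[, -N, drop = FALSE]) / 2
  dV <- diff(state$potential)
  -g * ions$valence * effective_diffusion(ions, geometry) *
    sweep(cbar, 2, dV, `*`)
}

#' Diffusive electrical current across every interface
#'
#' `I^d = F sum_k z_k J^d_k`: the net charge carried by the concentration-
#' gradient-driven fluxes. Nonzero whenever the ionic mobilities differ,
#' even for electroneutral concentration shifts.
#'
#' @inheritParams field_fluxes
#' @return numeric vector of length N-1, in A.
#' @export
diffusive_currents <- function(state, ions, geometry,
                               constants = physical_constants()) {
  as.numeric(constants$faraday *
               (ions$valence %*% diffusive_fluxes(state, ions, geometry)))
}

#' Field electrical current across every interface
#'
#' `I^f = F sum_k z_k J^f_k = -(alpha A_c / l_c) sigma (V_{n+1} - V_n)`:
#' the Ohmic current driven by the potential gradient.
#'
#' @inheritParams field_fluxes
#' @return numeric vector of length N-1, in A.
#' @export
field_currents <- function(state, ions, constants, geometry) {
  as.numeric(constants$faraday *
               (ions$valence %*% field_fluxes(state, ions, constants, geometry)))
}

#' Solver options
#'
#' @param dt explicit Euler time step in s.
#' @param include_diffusion if `FALSE`, diffusive fluxes are dropped from the
#'   continuity equation and diffusive currents from the potential solve,
#'   mimicking classical volume-conductor (drift-only) modelling.
#' @param duration total simulated time in s.
#' @param record_stride record potential/currents every this many steps.
#' @param conc_stride record concentration snapshots every this many steps
#'   (concentrations evolve slowly; default records 100x less often).
#' @param freeze_conductivity if `TRUE`, interface conductivities are pegged
#'   at their initial-state values for the whole run (diagnostic mode used to
#'   compare runs with identical Ohmic pathways).
#' @return an object of class `knp_options`.
#' @export
solver_options <- function(dt = 1e-4, include_diffusion = TRUE,
                           duration = 1, record_stride = 1L,
                           conc_stride = 100L * record_stride,
                           freeze_conductivity = FALSE) {
  stopifnot(dt > 0, duration > 0, record_stride >= 1, conc_stride >= 1)
  structure(list(dt = dt,
                 include_diffusion = isTRUE(include_diffusion),
                 duration = duration,
                 record_stride = as.integer(record_stride),
                 conc_stride = as.integer(conc_stride),
                 freeze_conductivity = isTRUE(freeze_conductivity)),
            class = "knp_options")
}

# explicit-diffusion stability check: max(D/lambda^2) dt / l_c^2 < 0.5
check_stability <- function(options, ions, geometry) {
  mu <- max(effective_diffusion(ions, geometry)) * options$dt /
    geometry$subvolume_height^2
  if (mu >= 0.5)
    stop(sprintf(paste0("time step dt = %g s violates the explicit-diffusion",
                        " stability bound (D dt / l_c^2 = %.3g >= 0.5)"),
                 options$dt, mu))
  invisible(mu)
}

#' Assemble the Kirchhoff current-law system for the potential
#'
#' Builds the tridiagonal linear system `A V = b` whose solution is the ECS
#' potential profile. Interior rows state that the net current into each
#' subvolume (transmembrane ionic + capacitive + diffusive + field) is zero;
#' row 1 pins the reference `V_1 = 0`; row N forbids net electrical current
#' into the deep reservoir (`I^d + I^f = 0` at the last interface).
#'
#' @param state a `knp_state` (supplies concentrations).
#' @param ions,geometry,constants matching configuration objects.
#' @param membrane_current per-subvolume net ionic transmembrane current
#'   `I^M_n` in A (length N).
#' @param capacitive_current per-subvolume capacitive current `I^cap_n` in A.
#' @param include_diffusion if `FALSE` diffusive currents are zeroed in the
#'   system (drift-only potential).
#' @param sigma optional per-interface conductivity vector (length N-1) to
#'   use instead of the state-derived one (frozen-conductivity runs).
#' @return an object of class `knp_potential_system`: list with the full
#'   `matrix` (N x N, tridiagonal) and `rhs`.
#' @export
assemble_potential_system <- function(state, ions, geometry, constants,
                                      membrane_current = NULL,
                                      capacitive_current = NULL,
                                      include_diffusion = TRUE,
                                      sigma = NULL) {
  N <- geometry$n_subvolumes
  if (is.null(membrane_current)) membrane_current <- rep(0, N)
  if (is.null(capacitive_current)) capacitive_current <- rep(0, N)
  stopifnot(length(membrane_current) == N, length(capacitive_current) == N)
  if (is.null(sigma))
    sigma <- interface_conductivities(state, ions, constants, geometry)
  stopifnot(length(sigma) == N - 1)
  if (all(sigma == 0))
    stop("all interface conductivities are zero: potential system is singular")
  Id <- if (include_diffusion)
    diffusive_currents(state, ions, geometry, constants)
  else rep(0, N - 1)

  scale <- geometry$subvolume_height /
    (geometry$volume_fraction * geometry$cross_section)

  A <- matrix(0, N, N)
  b <- numeric(N)
  # reference row
  A[1, 1] <- 1
  # interior rows: sigma_lo V_{n-1} - (sigma_lo+sigma_hi) V_n + sigma_hi V_{n+1}
  #   = scale * (-I_cap - I_M - Id_lo + Id_hi)
  for (n in 2:(N - 1)) {
    A[n, n - 1] <- sigma[n - 1]
    A[n, n]     <- -(sigma[n - 1] + sigma[n])
    A[n, n + 1] <- sigma[n]
    b[n] <- scale * (-capacitive_current[n] - membrane_current[n] -
                       Id[n - 1] + Id[n])
  }
  # top boundary: sigma (V_{N-1} - V_N) = -scale * Id_{N-1,N}
  # so that the field current exactly cancels the diffusive current there
  A[N, N - 1] <- sigma[N - 1]
  A[N, N]     <- -sigma[N - 1]
  b[N] <- -scale * Id[N - 1]
  structure(list(matrix = A, rhs = b), class = "knp_potential_system")
}

#' Solve the Kirchhoff potential system
#'
#' Direct elimination of the tridiagonal system (Thomas algorithm).
#'
#' @param system a `knp_potential_system`.
#' @return numeric vector of subvolume potentials in V, with `V[1] = 0`.
#' @export
solve_potential <- function(system) {
  stopifnot(inherits(system, "knp_potential_system"))
  A <- system$matrix
  N <- nrow(A)
  lower <- c(0, A[cbind(2:N, 1:(N - 1))])
  diago <- A[cbind(1:N, 1:N)]
  upper <- c(A[cbind(1:(N - 1), 2:N)], 0)
  tridiag_solve(lower, diago, upper, system$rhs)
}

# Thomas algorithm; errors on a numerically singular pivot
tridiag_solve <- function(lower, diago, upper, rhs) {
  N <- length(diago)
  cp <- numeric(N); dp <- numeric(N)
  piv <- diago[1]
  if (abs(piv) < .Machine$double.xmin) stop("singular potential system")
  cp[1] <- upper[1] / piv
  dp[1] <- rhs[1] / piv
  for (i in 2:N) {
    piv <- diago[i] - lower[i] * cp[i - 1]
    if (abs(piv) < .Machine$double.xmin) stop("singular potential system")
    cp[i] <- upper[i] / piv
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / piv
  }
  x <- numeric(N)
  x[N] <- dp[N]
  for (i in (N - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' One forward-Euler concentration update
#'
#' Applies the discretized continuity equation
#' `alpha A_c l_c dc/dt = J^M + J^d_in - J^d_out + J^f_in - J^f_out`
#' to the interior subvolumes (2..N-1); the edge boxes are constant
#' reservoirs and are never updated.
#'
#' @param state a `knp_state`.
#' @param diffusive,field flux matrices (n_ions x N-1) as returned by
#'   [diffusive_fluxes()] and [field_fluxes()].
#' @param ion_flux per-ion, per-subvolume transmembrane fluxes `J^M`
#'   (n_ions x N matrix, mol/s); `NULL` for none.
#' @param dt time step in s.
#' @param ions,geometry matching configuration objects.
#' @return the updated `knp_state` (time advanced by `dt`).
#' @export
step_concentrations <- function(state, diffusive, field, ion_flux = NULL,
                                dt, ions, geometry) {
  N <- geometry$n_subvolumes
  volume <- geometry$volume_fraction * geometry$cross_section *
    geometry$subvolume_height
  if (is.null(ion_flux)) ion_flux <- matrix(0, nrow(ions), N)
  interior <- 2:(N - 1)
  net <- ion_flux[, interior, drop = FALSE] +
    diffusive[, interior - 1, drop = FALSE] -
    diffusive[, interior, drop = FALSE] +
    field[, interior - 1, drop = FALSE] -
    field[, interior, drop = FALSE]
  conc <- state$concentrations
  conc[, interior] <- conc[, interior] + dt * net / volume
  if (any(conc < 0)) {
    bad <- which(conc < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("negative concentration for ion %s in subvolume %d",
                        " at t = %g s: reduce dt or check sources"),
                 rownames(conc)[bad[1]], bad[2], state$time + dt))
  }
  state$concentrations <- conc
  state$time <- state$time + dt
  state
}

#' Run a KNP simulation
#'
#' Advances the ECS state from `initial_state` (default: baseline) over
#' `options$duration`. Each step: (1) interface conductivities and diffusive
#' currents from the current concentrations, (2) assemble and solve the
#' Kirchhoff potential system with the current source sample (zero-order
#' hold between source samples), (3) Nernst-Planck fluxes, (4) forward-Euler
#' concentration update. Deterministic given its inputs.
#'
#' @param config list with `ions`, `geometry`, `constants` (see
#'   [default_configuration()]).
#' @param sources a `knp_sources` object (see [generate_population_sources()]
#'   and [read_source_series()]), or `NULL` for a source-free run.
#' @param options a `knp_options` object.
#' @param initial_state optional starting `knp_state`; defaults to baseline.
#' @return an object of class `knp_trajectory`: recorded `times`, `potential`
#'   (N x n_rec, V), per-interface `diffusive_current` and `field_current`
#'   (N-1 x n_rec, A), decimated concentration snapshots `conc_times` /
#'   `concentrations` (n_ions x N x n_conc), the final `state`, the worst
#'   relative Kirchhoff residual `worst_kcl_residual`, and the echoed
#'   `options`/`config`.
#' @export
run_simulation <- function(config, sources = NULL,
                           options = solver_options(), initial_state = NULL) {
  ions <- config$ions; geometry <- config$geometry
  constants <- config$constants
  N <- geometry$n_subvolumes
  K <- nrow(ions)
  check_stability(options, ions, geometry)
  if (!is.null(sources)) {
    stopifnot(inherits(sources, "knp_sources"))
    if (max(sources$times) + sources$sample_dt < options$duration - 1e-12)
      stop("source series does not cover the requested duration")
  }
  state <- if (is.null(initial_state)) baseline_state(ions, geometry)
  else initial_state
  dt <- options$dt
  nsteps <- as.integer(round(options$duration / dt))
  rec_idx <- seq(0L, nsteps, by = options$record_stride)
  conc_idx <- seq(0L, nsteps, by = options$conc_stride)
  n_rec <- length(rec_idx); n_conc <- length(conc_idx)

  Vrec <- matrix(NA_real_, N, n_rec)
  Idrec <- matrix(NA_real_, N - 1, n_rec)
  Ifrec <- matrix(NA_real_, N - 1, n_rec)
  Crec <- array(NA_real_, c(K, N, n_conc),
                dimnames = list(ions$name, NULL, NULL))
  t_rec <- rec_idx * dt
  t_conc <- conc_idx * dt
  ri <- 1L; ci <- 1L
  worst_res <- 0

  sigma0 <- interface_conductivities(state, ions, constants, geometry)
  zF <- constants$faraday * ions$valence

  for (i in 0:nsteps) {
    src <- sample_sources(sources, i * dt, K, N)
    I_M <- as.numeric(zF %*% src$ion_flux)
    sigma <- if (options$freeze_conductivity) sigma0
    else interface_conductivities(state, ions, constants, geometry)
    sys <- assemble_potential_system(
      state, ions, geometry, constants,
      membrane_current = I_M, capacitive_current = src$capacitive,
      include_diffusion = options$include_diffusion, sigma = sigma)
    state$potential <- solve_potential(sys)
    # Kirchhoff residual in current units, relative to the largest term
    res <- as.numeric(sys$matrix %*% state$potential - sys$rhs)
    sc <- max(abs(sys$rhs), abs(sigma) * max(abs(state$potential)), 1e-300)
    worst_res <- max(worst_res, max(abs(res)) / sc)

    Jd <- if (options$include_diffusion)
      diffusive_fluxes(state, ions, geometry)
    else matrix(0, K, N - 1)
    Jf <- field_fluxes(state, ions, constants, geometry)

    if (i %% options$record_stride == 0L) {
      Vrec[, ri] <- state$potential
      Idrec[, ri] <- as.numeric(zF %*% Jd)
      Ifrec[, ri] <- as.numeric(zF %*% Jf)
      ri <- ri + 1L
    }
    if (i %% options$conc_stride == 0L) {
      Crec[, , ci] <- state$concentrations
      ci <- ci + 1L
    }
    if (i < nsteps)
      state <- step_concentrations(state, Jd, Jf, src$ion_flux,
                                   dt, ions, geometry)
  }
  structure(list(times = t_rec, potential = Vrec,
                 diffusive_current = Idrec, field_current = Ifrec,
                 conc_times = t_conc, concentrations = Crec,
                 state = state, worst_kcl_residual = worst_res,
                 options = options, config = config),
            class = "knp_trajectory")
}

# zero-order hold sampling of a source series (NULL -> zero sources)
sample_sources <- function(sources, t, K, N) {
  if (is.null(sources))
    return(list(ion_flux = matrix(0, K, N), capacitive = numeric(N)))
  idx <- min(floor(t / sources$sample_dt + 1e-9) + 1, length(sources$times))
  list(ion_flux = matrix(sources$ion_fluxes[, , idx], K, N),
       capacitive = sources$capacitive[, idx])
}

#' @export
print.knp_trajectory <- function(x, ...) {
  cat("KNP trajectory:", length(x$times), "recorded instants over",
      format(max(x$times)), "s\n")
  cat("  potential range [mV]:",
      format(range(x$potential) * 1e3, digits = 4), "\n")
  cat("  worst relative Kirchhoff residual:",
      format(x$worst_kcl_residual, digits = 3), "\n")
  invisible(x)
}
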