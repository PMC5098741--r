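cfg <- knp_cfg
geom <- cfg$geometry
ions <- cfg$ions
const <- cfg$constants

test_that("interface conductivity follows its closed form", {
  c0 <- ions$baseline_concentration
  # K+-only hand evaluation: F^2 (D/lambda^2) c / (R T)
  kion <- ion_set("K", 1, 1.96e-9, 3)
  expect_equal(interface_conductivity(3, 3, kion, const, geom),
               96485^2 * (1.96e-9 / 1.6^2) * 3 / (8.314 * 300))
  expect_equal(interface_conductivity(rep(0, 4), rep(0, 4),
                                      ions, const, geom), 0)
  # arithmetic mean of the two sides
  expect_equal(interface_conductivity(c0, 3 * c0, ions, const, geom),
               interface_conductivity(2 * c0, 2 * c0, ions, const, geom))
  expect_error(interface_conductivity(-c0, c0, ions, const, geom),
               "non-negative")
  expect_equal(apparent_conductivity(1, geom), 0.2)
  expect_equal(apparent_conductivity(0, geom), 0)
})

test_that("diffusive fluxes are Fickian down-gradient", {
  st <- baseline_state(ions, geom)
  expect_equal(diffusive_fluxes(st, ions, geom),
               matrix(0, 4, 14), ignore_attr = TRUE)
  # +1 mol/m^3 K+ step between subvolumes 5 and 6: hand evaluation
  st$concentrations["K", 6:15] <- st$concentrations["K", 6:15] + 1
  J <- diffusive_fluxes(st, ions, geom)
  expect_equal(unname(J["K", 5]), -(600e-12 / 100e-6) * (1.96e-9 / 2.56) * 1)
  expect_equal(J["K", -5], rep(0, 13), ignore_attr = TRUE)
  # concentration increasing with depth -> negative (upward) flux
  st2 <- baseline_state(ions, geom)
  st2$concentrations["Na", ] <- seq(100, 150, length.out = 15)
  expect_true(all(diffusive_fluxes(st2, ions, geom)["Na", ] < 0))
})

test_that("field fluxes drive cations down-potential and match sigma", {
  st <- baseline_state(ions, geom)
  st$potential <- rep(0.01, 15)
  expect_equal(field_fluxes(st, ions, const, geom),
               matrix(0, 4, 14), ignore_attr = TRUE)
  st$potential <- seq(0, 0.01, length.out = 15)
  Jf <- field_fluxes(st, ions, const, geom)
  expect_true(all(Jf["K", ] < 0))   # cations move toward lower V
  expect_true(all(Jf["X", ] > 0))   # anions the other way
  # algebraic identity: F sum_k z_k J^f = -(alpha A_c / l_c) sigma dV,
  # on random states
  set.seed(11)
  for (i in 1:5) {
    stc <- ecs_state(matrix(runif(4 * 15, 0.5, 200), 4, 15),
                     potential = rnorm(15, sd = 1e-3),
                     ions = ions, geometry = geom)
    lhs <- field_currents(stc, ions, const, geom)
    sig <- interface_conductivity(stc$concentrations[, -15],
                                  stc$concentrations[, -1],
                                  ions, const, geom)
    g <- geom$volume_fraction * geom$cross_section / geom$subvolume_height
    expect_equal(lhs, -g * sig * diff(stc$potential), tolerance = 1e-12)
  }
})

test_that("diffusive currents vanish for equal-mobility electroneutral shifts", {
  st <- baseline_state(ions, geom)
  expect_equal(diffusive_currents(st, ions, geom, const), rep(0, 14))
  # equal D for all ions: an electroneutral shift carries no net charge
  eq_ions <- ion_set(ions$name, ions$valence, rep(1.5e-9, 4),
                     ions$baseline_concentration)
  st2 <- perturbed_state(list(ions = eq_ions, geometry = geom), 3,
                         soma_shifts)
  expect_equal(diffusive_currents(st2, eq_ions, geom, const), rep(0, 14),
               tolerance = 1e-20)
  # soma-shift profile: direct hand evaluation at the interfaces of box 3
  st3 <- perturbed_state(cfg, 3, soma_shifts)
  Id <- diffusive_currents(st3, ions, geom, const)
  shifts_ordered <- soma_shifts[ions$name]
  hand <- 96485 * sum(ions$valence * ions$diffusion_constant / 1.6^2 *
                        shifts_ordered) * (600e-12 / 100e-6)
  expect_equal(Id[2], -hand)   # into box 3 from box 2: against the step
  expect_equal(Id[3], hand)
  expect_equal(Id[-c(2, 3)], rep(0, 12))
})

test_that("potential system encodes Kirchhoff's law with reservoir rows", {
  st <- baseline_state(ions, geom)
  sys <- assemble_potential_system(st, ions, geom, const)
  expect_equal(sys$matrix[1, ], c(1, rep(0, 14)))
  expect_equal(sys$rhs, rep(0, 15))
  expect_equal(solve_potential(sys), rep(0, 15))
  # interior rows of the sigma coefficients sum to zero
  expect_equal(rowSums(sys$matrix)[2:14], rep(0, 13), tolerance = 1e-12)
  # diffusion off, no sources: V = 0 for arbitrary concentrations
  set.seed(3)
  stc <- ecs_state(matrix(runif(4 * 15, 1, 100), 4, 15),
                   ions = ions, geometry = geom)
  sys2 <- assemble_potential_system(stc, ions, geom, const,
                                    include_diffusion = FALSE)
  expect_equal(solve_potential(sys2), rep(0, 15))
  expect_error(assemble_potential_system(
    ecs_state(matrix(0, 4, 15), ions = ions, geometry = geom),
    ions, geom, const), "singular")
})

test_that("tridiagonal solve agrees with a dense solver and has tiny residual", {
  set.seed(21)
  for (i in 1:10) {
    stc <- ecs_state(matrix(runif(4 * 15, 1, 200), 4, 15),
                     ions = ions, geometry = geom)
    I_M <- c(0, rnorm(13, sd = 1e-9), 0)
    I_cap <- c(0, rnorm(13, sd = 1e-9), 0)
    sys <- assemble_potential_system(stc, ions, geom, const,
                                     membrane_current = I_M,
                                     capacitive_current = I_cap)
    V <- solve_potential(sys)
    expect_equal(V, as.numeric(solve(sys$matrix, sys$rhs)),
                 tolerance = 1e-10)
    expect_equal(V[1], 0)
    resid <- sys$matrix %*% V - sys$rhs
    expect_lt(max(abs(resid)) / max(abs(sys$rhs)), 1e-10)
  }
})

test_that("after a solve, field currents close Kirchhoff's law per subvolume", {
  st <- perturbed_state(cfg, 3, soma_shifts)
  I_M <- c(0, rnorm(13, sd = 1e-9), 0)
  I_cap <- -I_M   # depth-balanced
  sys <- assemble_potential_system(st, ions, geom, const,
                                   membrane_current = I_M,
                                   capacitive_current = I_cap)
  st$potential <- solve_potential(sys)
  Id <- diffusive_currents(st, ions, geom, const)
  If <- field_currents(st, ions, const, geom)
  net <- -I_cap[2:14] - I_M[2:14] - Id[1:13] + Id[2:14] - If[1:13] + If[2:14]
  expect_lt(max(abs(net)) / max(abs(c(Id, If))), 1e-10)
  # top boundary: no net electrical current into the deep reservoir
  expect_lt(abs(Id[14] + If[14]), 1e-12 * max(abs(c(Id, If)), 1e-300))
})

test_that("concentration stepping integrates the continuity equation", {
  st <- baseline_state(ions, geom)
  zeroJ <- matrix(0, 4, 14)
  st2 <- step_concentrations(st, zeroJ, zeroJ, NULL, 1e-4, ions, geom)
  expect_equal(st2$concentrations, st$concentrations)
  expect_equal(st2$time, 1e-4)
  # constant influx: linear growth c(t) = c0 + J t / (alpha A_c l_c)
  JM <- matrix(0, 4, 15, dimnames = list(ions$name, NULL))
  JM["K", 5] <- 2e-12
  stt <- st
  for (i in 1:50)
    stt <- step_concentrations(stt, zeroJ, zeroJ, JM, 1e-3, ions, geom)
  vol <- 0.2 * 3000e-12 * 100e-6
  expect_equal(unname(stt$concentrations["K", 5]), 3 + 2e-12 * 0.05 / vol,
               tolerance = 1e-12)
  # diffusion-only relaxation with zeroed edge fluxes conserves interior
  # ion content
  stp <- perturbed_state(cfg, 8, c(K = 2))
  stq <- perturbed_state(cfg, 9, c(K = 2))
  stp$concentrations <- (stp$concentrations + stq$concentrations) / 2
  total0 <- rowSums(stp$concentrations[, 2:14])
  for (i in 1:200) {
    Jd <- diffusive_fluxes(stp, ions, geom)
    Jd[, c(1, 14)] <- 0
    stp <- step_concentrations(stp, Jd, zeroJ, NULL, 1e-3, ions, geom)
  }
  expect_equal(rowSums(stp$concentrations[, 2:14]), total0,
               tolerance = 1e-12)
  # a flux that would drive concentrations negative raises a located error
  JM2 <- matrix(0, 4, 15, dimnames = list(ions$name, NULL))
  JM2["Ca", 7] <- -1e-6
  expect_error(step_concentrations(st, zeroJ, zeroJ, JM2, 1e-3, ions, geom),
               "Ca.*subvolume 7")
})

test_that("time step stability bound is enforced", {
  expect_error(run_simulation(cfg, NULL,
                              solver_options(dt = 10, duration = 20)),
               "stability")
})

test_that("source-free baseline run stays exactly at rest", {
  traj <- run_simulation(cfg, NULL,
                         solver_options(dt = 1e-3, duration = 0.02))
  expect_equal(max(abs(traj$potential)), 0)
  expect_equal(traj$state$concentrations,
               baseline_state(ions, geom)$concentrations)
})

test_that("decay scenario: first-step potential peaks in the perturbed box", {
  st0 <- perturbed_state(cfg, 3, soma_shifts)
  traj <- run_simulation(cfg, NULL,
                         solver_options(dt = 1e-4, duration = 0.01),
                         initial_state = st0)
  expect_equal(traj$potential[3, 1] * 1e3, -0.17, tolerance = 0.02)
  expect_equal(which.min(traj$potential[, 1]), 3)
  # diffusion off: potential identically zero, concentrations frozen
  trn <- run_simulation(cfg, NULL,
                        solver_options(dt = 1e-4, duration = 0.01,
                                       include_diffusion = FALSE),
                        initial_state = st0)
  expect_equal(max(abs(trn$potential)), 0)
  expect_equal(trn$state$concentrations, st0$concentrations)
})

test_that("per-step Kirchhoff residual stays below 1e-10 with random sources", {
  src <- random_electroneutral_sources(cfg, duration = 0.02,
                                       sample_dt = 1e-3, seed = 5)
  traj <- run_simulation(cfg, src, solver_options(dt = 1e-3, duration = 0.02))
  expect_lt(traj$worst_kcl_residual, 1e-10)
  # top-boundary zero net current at every recorded instant
  top <- traj$diffusive_current[14, ] + traj$field_current[14, ]
  scale <- max(abs(traj$field_current), 1e-300)
  expect_lt(max(abs(top)) / scale, 1e-10)
})

test_that("charge bookkeeping: ionic charge gain equals -I_cap dt", {
  src <- random_electroneutral_sources(cfg, duration = 0.01,
                                       sample_dt = 1e-3, seed = 9)
  opts <- solver_options(dt = 1e-3, duration = 0.01,
                         record_stride = 1, conc_stride = 1)
  traj <- run_simulation(cfg, src, opts)
  vol <- geom$volume_fraction * geom$cross_section * geom$subvolume_height
  zF <- const$faraday * ions$valence
  for (j in 1:5) {
    dq <- as.numeric(zF %*% (traj$concentrations[, , j + 1] -
                               traj$concentrations[, , j])) * vol
    Icap <- src$capacitive[, j]
    expect_equal(dq, -Icap * opts$dt, tolerance = 1e-8)
  }
})

test_that("total interface current is mode-independent for fixed sources", {
  src <- random_electroneutral_sources(cfg, duration = 0.02,
                                       sample_dt = 1e-3, seed = 13)
  base <- solver_options(dt = 1e-3, duration = 0.02,
                         freeze_conductivity = TRUE)
  on_ <- run_simulation(cfg, src, base)
  base$include_diffusion <- FALSE
  off <- run_simulation(cfg, src, base)
  total_on <- on_$diffusive_current + on_$field_current
  total_off <- off$field_current
  scale <- max(abs(total_on))
  expect_lt(max(abs(total_on - total_off)) / scale, 1e-6)
})

test_that("halving dt gives first-order convergence of the potential", {
  st0 <- perturbed_state(cfg, 3, soma_shifts)
  v_at <- function(dt) {
    run_simulation(cfg, NULL,
                   solver_options(dt = dt, duration = 0.4,
                                  record_stride = round(0.4 / dt)),
                   initial_state = st0)$potential[3, 2]
  }
  v1 <- v_at(4e-3); v2 <- v_at(2e-3); v3 <- v_at(1e-3)
  ratio <- abs(v1 - v2) / abs(v2 - v3)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3)
})

test_that("relaxed two-compartment junction matches Henderson and GHK", {
  # small (<= 5%) electroneutral monovalent shifts (GHK excludes divalents);
  # quasi-steady junction from the Kirchhoff solve, compared with the
  # closed-form junction potentials
  small <- c(Na = -5.1, K = 6.0, X = 0.9) * 0.02   # K+ shift 4% of baseline
  st0 <- perturbed_state(cfg, 3, small)
  traj <- run_simulation(cfg, NULL, solver_options(dt = 1e-4, duration = 1e-3),
                         initial_state = st0)
  v_knp <- traj$potential[3, 1]
  b <- baseline_named
  s <- b; s[names(small)] <- s[names(small)] + small
  v_ghk <- ghk_potential(b, s, ions, const)
  v_hen <- henderson_potential(b, s, ions, const)
  expect_equal(v_knp / v_ghk, 1, tolerance = 0.01)
  expect_equal(v_knp / v_hen, 1, tolerance = 0.01)
})
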