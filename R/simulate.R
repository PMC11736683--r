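# Synthetic Brownian-dynamics generators. These stand in for a molecular-
# dynamics engine: they produce trajectories with the exact statistical
# structure the analysis stages assume (Boltzmann stationary laws, known
# diffusivities, known well depths), so every estimator can be validated
# against its own input.

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Coerce a free-energy / diffusivity specification to a function of z.
# Accepts a function, a single number (constant), NULL (zero), or a
# two-column table (z, value) interpolated with a periodic cubic spline.
as_profile_fun <- function(f, what = "profile") {
  if (is.null(f)) return(function(z) rep(0, length(z)))
  if (is.function(f)) return(f)
  if (is.numeric(f) && length(f) == 1L) {
    val <- f
    return(function(z) rep(val, length(z)))
  }
  tab <- as.data.frame(f)
  if (ncol(tab) < 2L) stop(what, " table needs two columns (z, value)")
  z <- tab[[1]]; v <- tab[[2]]
  if (abs(v[1] - v[length(v)]) > 1e-9)
    stop(what, " table must be periodic-consistent (first value == last)")
  stats::splinefun(z, v, method = "periodic")
}

#' Specification of a 1D membrane-permeation surrogate system
#'
#' Describes an overdamped Langevin (Brownian) particle diffusing on a
#' periodic 1D free-energy profile `F(z)` with position-dependent
#' diffusivity `D(z)` — a surrogate for a permeant moving along the membrane
#' normal. The Ito convention with the spurious-drift term `D'(z)` is used,
#' so the stationary distribution is exactly `exp(-F/kBT)` whatever `D`.
#'
#' @param F free energy in kJ/mol: a function of z, a constant, `NULL`
#'   (flat), or a two-column table (z, F) interpolated with a periodic
#'   cubic spline. Must satisfy `F(-box_z/2) == F(+box_z/2)` within 1e-9.
#' @param D diffusivity in A^2/ps: a function of z, a constant, or a table;
#'   must be positive everywhere
#' @param box_z periodic box length along z (angstrom)
#' @param dt time step (ps)
#' @param n_steps number of integration steps
#' @param n_particles number of independent particles
#' @param seed integer RNG seed (the generator never touches the caller's
#'   RNG stream)
#' @param temperature temperature in K (default 310)
#' @param save_every store every `save_every`-th step (default 1)
#' @return a `permeation_spec` list, validated
#' @export
permeation_spec <- function(F = NULL, D = 0.5, box_z = 60, dt = 1,
                            n_steps = 1e5, n_particles = 1, seed = 1,
                            temperature = 310, save_every = 1) {
  stopifnot(box_z > 0, dt > 0, n_steps >= 0, n_particles >= 1,
            temperature > 0, save_every >= 1)
  Ffun <- as_profile_fun(F, "free-energy")
  Dfun <- as_profile_fun(D, "diffusivity")
  if (abs(Ffun(-box_z / 2) - Ffun(box_z / 2)) > 1e-9)
    stop("F must be periodic-consistent at the box edges: |F(-L/2) - F(+L/2)| < 1e-9")
  spec <- list(F = Ffun, D = Dfun, box_z = box_z, dt = dt,
               n_steps = as.integer(n_steps),
               n_particles = as.integer(n_particles),
               seed = as.integer(seed), temperature = temperature,
               save_every = as.integer(save_every))
  class(spec) <- "permeation_spec"
  spec
}

#' Simulate 1D permeation on a free-energy profile
#'
#' Overdamped Langevin dynamics (Ito update)
#' `z <- z + [-D F'/(kB T) + D'] dt + sqrt(2 D dt) N(0,1)`,
#' periodic in z. Initial positions are drawn from the Boltzmann law
#' `exp(-F/kBT)`, so the chain is stationary from the first frame. Wrapped
#' and unwrapped z are both stored; x and y are zero with a nominal 1 A
#' box edge, so lateral area bookkeeping in the permeability module is
#' well-defined for 1D systems.
#'
#' @param spec a [permeation_spec()]
#' @return a `memgas_traj` with all particles labeled `"permeant"`; the
#'   generating spec is attached as attribute `"spec"`
#' @examples
#' sp <- permeation_spec(D = 0.5, box_z = 30, n_steps = 1000, seed = 42)
#' tr <- simulate_permeation_1d(sp)
#' n_frames(tr)
#' @export
simulate_permeation_1d <- function(spec) {
  stopifnot(inherits(spec, "permeation_spec"))
  L <- spec$box_z
  kT <- kBT(spec$temperature)
  ng <- 4097L
  zg <- seq(-L / 2, L / 2, length.out = ng)
  Fg <- spec$F(zg)
  Dg <- spec$D(zg)
  if (any(!is.finite(Fg))) stop("F must be finite on the box")
  if (any(Dg <= 0)) stop("D(z) must be > 0 everywhere")
  # periodic splines give analytic derivatives of the (interpolated) inputs
  Fsp <- stats::splinefun(zg, c(Fg[-ng], Fg[1]), method = "periodic")
  Dsp <- stats::splinefun(zg, c(Dg[-ng], Dg[1]), method = "periodic")
  drift <- -Dg * Fsp(zg, deriv = 1) / kT + Dsp(zg, deriv = 1)
  if (max(abs(drift)) * spec$dt > L / 4)
    stop("stability: time step too large (max single-step drift exceeds box_z/4); ",
         "reduce dt or smooth F")
  res <- local_seed(spec$seed, {
    w <- exp(-(Fg - min(Fg)) / kT)
    z0 <- sample(zg, spec$n_particles, replace = TRUE, prob = w) +
      stats::runif(spec$n_particles, -L / (2 * (ng - 1)), L / (2 * (ng - 1)))
    .langevin_1d_cpp(z0, spec$n_steps, spec$save_every, spec$dt, L,
                     drift, Dg)
  })
  n_saved <- nrow(res$z_wrapped)
  np <- spec$n_particles
  xyz <- array(0, dim = c(n_saved, np, 3L))
  xyz[, , 3] <- res$z_wrapped
  xyz_u <- array(0, dim = c(n_saved, np, 3L))
  xyz_u[, , 3] <- res$z_unwrapped
  out <- trajectory(times = spec$dt * spec$save_every * (seq_len(n_saved) - 1),
                    xyz = xyz, box = c(1, 1, L), labels = "permeant",
                    xyz_unwrapped = xyz_u,
                    periodic = c(FALSE, FALSE, TRUE))
  attr(out, "spec") <- spec
  out
}

#' Specification of a 3D cavity-binding surrogate system
#'
#' A particle performing a Metropolis random walk in a periodic cubic box
#' containing spherical square wells of known depth — a surrogate for a gas
#' molecule binding to protein cavities. Metropolis dynamics handles the
#' discontinuous square-well potential exactly, so the stationary in/out
#' number-density ratio per well is exactly `exp(depth/kBT)`; its kinetics
#' are only qualitatively diffusive (use occupancy ratios, not residence
#' times, for quantitative checks).
#'
#' @param box cubic box edge (angstrom)
#' @param wells data.frame with columns `x`, `y`, `z`, `radius`, `depth`
#'   (angstrom, angstrom, kJ/mol); wells must be pairwise non-overlapping
#' @param D nominal diffusivity (A^2/ps) used to pick the default proposal
#'   scale and for time bookkeeping
#' @param step_size Gaussian proposal scale (angstrom); default
#'   `sqrt(2 * D * dt)`
#' @param dt nominal time per Metropolis step (ps), used for downstream
#'   time bookkeeping
#' @inheritParams permeation_spec
#' @return a `binding_spec` list, validated
#' @export
binding_spec <- function(box = 30, wells, D = 0.5, step_size = NULL,
                         dt = 1, n_steps = 1e5, n_particles = 1, seed = 1,
                         temperature = 310, save_every = 1) {
  stopifnot(box > 0, dt > 0, n_steps >= 0, n_particles >= 1,
            temperature > 0, save_every >= 1)
  wells <- as.data.frame(wells)
  need <- c("x", "y", "z", "radius", "depth")
  if (!all(need %in% names(wells)))
    stop("`wells` needs columns: ", paste(need, collapse = ", "))
  stopifnot(all(wells$radius > 0), all(wells$depth >= 0))
  nw <- nrow(wells)
  if (nw >= 2L) {
    for (i in seq_len(nw - 1L)) for (j in seq((i + 1L), nw)) {
      d <- wells[i, c("x", "y", "z")] - wells[j, c("x", "y", "z")]
      d <- wrap_centered(as.numeric(d), box)
      if (sqrt(sum(d^2)) <= wells$radius[i] + wells$radius[j])
        stop("wells ", i, " and ", j, " overlap")
    }
  }
  if (is.null(step_size)) step_size <- sqrt(2 * D * dt)
  stopifnot(step_size > 0)
  spec <- list(box = box, wells = wells, D = D, step_size = step_size,
               dt = dt, n_steps = as.integer(n_steps),
               n_particles = as.integer(n_particles),
               seed = as.integer(seed), temperature = temperature,
               save_every = as.integer(save_every))
  class(spec) <- "binding_spec"
  spec
}

#' Simulate binding to spherical square wells
#'
#' @param spec a [binding_spec()]
#' @return a `memgas_traj` with all particles labeled `"permeant"`; the
#'   generating spec is attached as attribute `"spec"`
#' @seealso [binding_spec()] for the dynamics and its stationary law
#' @export
simulate_binding_3d <- function(spec) {
  stopifnot(inherits(spec, "binding_spec"))
  kT <- kBT(spec$temperature)
  centers <- as.matrix(spec$wells[, c("x", "y", "z")])
  res <- local_seed(spec$seed, {
    x0 <- matrix(stats::runif(3L * spec$n_particles,
                              -spec$box / 2, spec$box / 2),
                 ncol = 3L)
    .metropolis_3d_cpp(x0, spec$n_steps, spec$save_every, spec$box,
                       spec$step_size, centers, spec$wells$radius,
                       spec$wells$depth, kT)
  })
  n_saved <- dim(res$xyz_wrapped)[1]
  out <- trajectory(times = spec$dt * spec$save_every * (seq_len(n_saved) - 1),
                    xyz = res$xyz_wrapped, box = rep(spec$box, 3L),
                    labels = "permeant", xyz_unwrapped = res$xyz_unwrapped,
                    periodic = c(TRUE, TRUE, TRUE))
  attr(out, "spec") <- spec
  out
}

#' Simulate free 3D Brownian diffusion in a periodic box
#'
#' Independent Brownian particles with constant diffusivity; wrapped and
#' unwrapped coordinates are both stored, so the MSD module can be run
#' directly on the output.
#'
#' @param D diffusivity (A^2/ps)
#' @param box cubic box edge or length-3 edge vector (angstrom)
#' @param n_particles number of independent particles
#' @param dt time step (ps)
#' @param n_steps number of steps (0 gives a single-frame trajectory)
#' @param seed integer RNG seed
#' @param save_every store every `save_every`-th step
#' @return a `memgas_traj` with all particles labeled `"permeant"`
#' @examples
#' tr <- simulate_free_3d(D = 0.5, box = 50, n_particles = 3,
#'                        dt = 1, n_steps = 100, seed = 7)
#' @export
simulate_free_3d <- function(D, box = 100, n_particles = 1, dt = 1,
                             n_steps = 1e4, seed = 1, save_every = 1) {
  stopifnot(D > 0, dt > 0, n_steps >= 0, n_particles >= 1, save_every >= 1)
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(length(box) == 3L, all(box > 0))
  res <- local_seed(seed, {
    x0 <- cbind(stats::runif(n_particles, -box[1] / 2, box[1] / 2),
                stats::runif(n_particles, -box[2] / 2, box[2] / 2),
                stats::runif(n_particles, -box[3] / 2, box[3] / 2))
    .free_3d_cpp(x0, as.integer(n_steps), as.integer(save_every), dt, box, D)
  })
  n_saved <- dim(res$xyz_wrapped)[1]
  out <- trajectory(times = dt * save_every * (seq_len(n_saved) - 1),
                    xyz = res$xyz_wrapped, box = box, labels = "permeant",
                    xyz_unwrapped = res$xyz_unwrapped,
                    periodic = c(TRUE, TRUE, TRUE))
  attr(out, "D_input") <- D
  out
}
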