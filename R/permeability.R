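#' Membrane geometry: dividing surfaces
#'
#' The membrane slab is delimited by two dividing surfaces at z = -h/2 and
#' z = +h/2. For membrane trajectories `dividing_surfaces()` places them at
#' the time-and-particle mean of |z| of the phosphate-labeled particles
#' plus an offset (8 angstrom by default), so the whole membrane thickness
#' is covered. For synthetic systems, construct the geometry directly with
#' `membrane_geometry()`.
#'
#' @param traj a `memgas_traj` with phosphate-labeled particles
#' @param offset distance added beyond the mean phosphate |z| (angstrom)
#' @return a `membrane_geometry` with `h2` (= h/2), `offset`, and
#'   `phosphate_mean_abs_z`
#' @examples
#' membrane_geometry(h2 = 27.3)
#' @export
dividing_surfaces <- function(traj, offset = 8) {
  stopifnot(is_trajectory(traj))
  ip <- particles_with_role(traj, "phosphate")
  if (length(ip) == 0L)
    stop("trajectory has no phosphate-labeled particles; ",
         "use membrane_geometry() to set h/2 directly")
  traj <- recenter_membrane(traj)
  zp <- abs(traj$xyz[, ip, 3])
  membrane_geometry(phosphate_mean_abs_z = mean(zp), offset = offset)
}

#' @rdname dividing_surfaces
#' @param h2 half membrane thickness h/2 (angstrom); if missing, computed
#'   as `phosphate_mean_abs_z + offset`
#' @param phosphate_mean_abs_z mean |z| of the phosphates (angstrom)
#' @export
membrane_geometry <- function(h2 = NULL, phosphate_mean_abs_z = NULL,
                              offset = 8) {
  if (is.null(h2)) {
    if (is.null(phosphate_mean_abs_z))
      stop("either `h2` or `phosphate_mean_abs_z` must be given")
    h2 <- phosphate_mean_abs_z + offset
  }
  stopifnot(is.numeric(h2), length(h2) == 1L, h2 > 0)
  structure(list(h2 = h2, offset = offset,
                 phosphate_mean_abs_z = phosphate_mean_abs_z),
            class = "membrane_geometry")
}

#' @export
print.membrane_geometry <- function(x, ...) {
  cat("<membrane_geometry> dividing surfaces at z = +/-", format(x$h2),
      "A\n")
  if (!is.null(x$phosphate_mean_abs_z))
    cat("  mean phosphate |z| =", format(x$phosphate_mean_abs_z),
        "A + offset", format(x$offset), "A\n")
  invisible(x)
}

#' Detect full membrane crossings
#'
#' Frames are labeled A (z < -h/2), M (|z| <= h/2) or B (z > +h/2). For
#' each permeant, a crossing is recorded whenever the most recent water
#' label (A or B) is followed by the opposite water label; excursions into
#' M that return to the same side do not count. `t_entry` is the last frame
#' in the origin water region and `t_exit` the first frame in the
#' destination region. Frame-to-frame jumps between A and B with
#' |dz| > Lz/2 are periodic wraps through the contiguous water phase and
#' are not crossings.
#'
#' @param traj a `memgas_traj` with membrane-centered z coordinates
#' @param geom a `membrane_geometry`
#' @return data.frame with columns `particle`, `t_entry` (ps), `t_exit`
#'   (ps), `direction` (`"+z"` or `"-z"`)
#' @export
detect_crossings <- function(traj, geom) {
  stopifnot(is_trajectory(traj), inherits(geom, "membrane_geometry"))
  traj <- recenter_membrane(traj)
  Lz <- traj$box[1, 3]
  if (geom$h2 >= Lz / 2)
    stop("geometry error: h/2 (", geom$h2, " A) must be smaller than half ",
         "the box (", Lz / 2, " A)")
  ip <- particles_with_role(traj, "permeant")
  if (length(ip) == 0L) stop("trajectory has no permeant-labeled particles")
  times <- traj$times
  out <- vector("list", length(ip))
  for (j in seq_along(ip)) {
    z <- wrap_centered(traj$xyz[, ip[j], 3], Lz)
    lab <- integer(length(z))
    lab[z < -geom$h2] <- -1L
    lab[z > geom$h2] <- 1L
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    last_w <- 0L
    last_w_end <- NA_integer_
    ev_entry <- numeric(0); ev_exit <- numeric(0); ev_dir <- character(0)
    for (k in seq_along(r$values)) {
      s <- r$values[k]
      if (s == 0L) next
      if (last_w != 0L && s != last_w) {
        direct <- k > 1L && r$values[k - 1L] == last_w
        is_wrap <- FALSE
        if (direct) {
          dz <- z[starts[k]] - z[ends[k - 1L]]
          is_wrap <- abs(dz) > Lz / 2
        }
        if (!is_wrap) {
          ev_entry <- c(ev_entry, times[last_w_end])
          ev_exit <- c(ev_exit, times[starts[k]])
          ev_dir <- c(ev_dir, if (last_w == -1L) "+z" else "-z")
        }
      }
      last_w <- s
      last_w_end <- ends[k]
    }
    out[[j]] <- if (length(ev_entry))
      data.frame(particle = ip[j], t_entry = ev_entry, t_exit = ev_exit,
                 direction = ev_dir)
    else NULL
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(particle = integer(0), t_entry = numeric(0),
                      t_exit = numeric(0), direction = character(0))
  out
}

#' Counting-method permeability
#'
#' Equilibrium permeability from the number of full membrane crossings:
#' `P = n_crossings / (2 A t_sim c_water)`, where A is the mean lateral box
#' area, `t_sim` the trajectory time span, and `c_water` the mean permeant
#' number density in the water phase |z| > h/2. The factor 2 accounts for
#' crossings being counted in both directions. Reported in cm/s
#' (1 A/ps = 1e4 cm/s). For 1D synthetic systems the generators set the
#' lateral box edges to 1 angstrom, so A = 1 A^2 consistently in both the
#' numerator and `c_water`.
#'
#' The default error bar is Poisson, `P_err = P / sqrt(n_crossings)`
#' (`NA` when there are no crossings, in which case P = 0).
#'
#' @param traj a `memgas_traj`
#' @param geom a `membrane_geometry`; if `NULL`, derived from the phosphate
#'   labels via [dividing_surfaces()]
#' @param offset passed to [dividing_surfaces()] when `geom` is `NULL`
#' @return a `perm_result` with `P` and `P_err` (cm/s), `n_crossings`,
#'   `events`, `area` (A^2), `sim_time` (ps), `c_water` (1/A^3), `h2` (A)
#' @examples
#' sp <- permeation_spec(D = 0.5, box_z = 60, n_steps = 50000, seed = 11)
#' tr <- simulate_permeation_1d(sp)
#' counting_permeability(tr, membrane_geometry(h2 = 20))
#' @export
counting_permeability <- function(traj, geom = NULL, offset = 8) {
  stopifnot(is_trajectory(traj))
  if (is.null(geom)) geom <- dividing_surfaces(traj, offset = offset)
  traj <- recenter_membrane(traj)
  nf <- n_frames(traj)
  if (nf < 2L) stop("permeability needs sim_time > 0 (at least two frames)")
  Lz <- traj$box[1, 3]
  events <- detect_crossings(traj, geom)
  n <- nrow(events)
  A <- mean(traj$box[, 1] * traj$box[, 2])
  sim_time <- traj$times[nf] - traj$times[1]
  ip <- particles_with_role(traj, "permeant")
  zw <- wrap_centered(traj$xyz[, ip, 3, drop = FALSE], Lz)
  n_water <- rowSums(abs(array(zw, dim = c(nf, length(ip)))) > geom$h2)
  water_len <- Lz - 2 * geom$h2
  c_water <- mean(n_water) / (A * water_len)
  if (c_water <= 0)
    stop("zero permeant occupancy in the water phase; ",
         "c_water is undefined")
  P_Aps <- n / (2 * A * sim_time * c_water)
  P <- P_Aps * .memgas$A_per_ps_to_cm_per_s
  P_err <- if (n > 0) P / sqrt(n) else NA_real_
  structure(list(n_crossings = n, events = events, area = A,
                 sim_time = sim_time, c_water = c_water, h2 = geom$h2,
                 P = P, P_err = P_err, units = "cm/s"),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("<perm_result> ", x$n_crossings, " crossings in ",
      format(x$sim_time), " ps, h/2 = ", format(x$h2), " A\n", sep = "")
  cat(sprintf("  c_water = %.4g / A^3, area = %.4g A^2\n",
              x$c_water, x$area))
  if (is.na(x$P_err))
    cat(sprintf("  P = %.4g cm/s (error undefined: no crossings)\n", x$P))
  else
    cat(sprintf("  P = %.4g +/- %.3g cm/s (Poisson)\n", x$P, x$P_err))
  invisible(x)
}

#' Permeability from the inhomogeneous solubility-diffusivity model
#'
#' The Smoluchowski-based permeability integral combining energetic and
#' kinetic contributions:
#' `1/P = integral_{-h/2}^{+h/2} exp(F(z)/kBT) / D(z) dz`,
#' evaluated by adaptive quadrature. `F` must be referenced to 0 in the
#' water phase. Used as the closed-form oracle against which the counting
#' method is validated.
#'
#' @param F free energy in kJ/mol: function of z, constant, or table
#' @param D diffusivity in A^2/ps: function of z, constant, or table;
#'   must be positive on the membrane interval
#' @param geom a `membrane_geometry` (or a bare h/2 value in angstrom)
#' @param temperature temperature in K
#' @param rel_tol relative quadrature tolerance (default 1e-8)
#' @return permeability in cm/s
#' @examples
#' isd_permeability(F = 0, D = 0.5, geom = membrane_geometry(h2 = 20))
#' # = D/h = 0.0125 A/ps = 125 cm/s
#' @export
isd_permeability <- function(F, D, geom, temperature = 310,
                             rel_tol = 1e-8) {
  if (is.numeric(geom) && length(geom) == 1L)
    geom <- membrane_geometry(h2 = geom)
  stopifnot(inherits(geom, "membrane_geometry"))
  Ffun <- as_profile_fun(F, "free-energy")
  Dfun <- as_profile_fun(D, "diffusivity")
  kT <- kBT(temperature)
  zs <- seq(-geom$h2, geom$h2, length.out = 513L)
  if (any(Dfun(zs) <= 0)) stop("D(z) must be > 0 on [-h/2, +h/2]")
  integrand <- function(z) exp(Ffun(z) / kT) / Dfun(z)
  res <- stats::integrate(integrand, -geom$h2, geom$h2, rel.tol = rel_tol,
                          subdivisions = 1000L)
  (1 / res$value) * .memgas$A_per_ps_to_cm_per_s
}
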