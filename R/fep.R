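#' Free-energy profile along the membrane normal
#'
#' Boltzmann inversion of the permeant positional histogram:
#' `F(z) = -kB T ln(hist(z))`, with the profile shifted so that its mean
#' over the water region is zero. Empty bins are reported as `NA`, never as
#' infinities, so downstream code can treat them as missing data.
#'
#' Bins default to 0.5 angstrom width covering the box z-range; the
#' profile is not symmetrized across z = 0 (both leaflets are kept, so
#' block errors can expose sampling asymmetry). When the trajectory carries
#' phosphate labels the membrane midplane is recentered to z = 0 per frame
#' first.
#'
#' @param traj a `memgas_traj` with at least one permeant
#' @param bin_width histogram bin width in angstrom (default 0.5); ignored
#'   when `breaks` is given
#' @param breaks optional explicit bin edges (angstrom), must cover the box
#'   z-range
#' @param water_region length-2 numeric `c(lo, hi)`: bins whose center
#'   satisfies `lo <= |z| <= hi` define the water phase used as the F = 0
#'   reference
#' @param temperature temperature in K
#' @param units `"kJ/mol"` (default) or `"kBT"` for the reported profile
#' @param n_blocks if >= 2, per-bin standard errors from block averaging
#'   with this many contiguous blocks (default 10); 0 skips error bars
#' @return an `fe_profile` with `bin_centers`, `F`, `F_err`, `counts`,
#'   `water_region`, `temperature`, `units`
#' @examples
#' sp <- permeation_spec(D = 1, box_z = 30, n_steps = 20000, seed = 3)
#' tr <- simulate_permeation_1d(sp)
#' pr <- free_energy_profile(tr, water_region = c(10, 15), n_blocks = 5)
#' @export
free_energy_profile <- function(traj, bin_width = 0.5, breaks = NULL,
                                water_region, temperature = 310,
                                units = c("kJ/mol", "kBT"), n_blocks = 10) {
  stopifnot(is_trajectory(traj))
  units <- match.arg(units)
  traj <- recenter_membrane(traj)
  ip <- particles_with_role(traj, "permeant")
  if (length(ip) == 0L) stop("trajectory has no permeant-labeled particles")
  Lz <- traj$box[1, 3]
  if (is.null(breaks)) {
    nb <- max(1L, ceiling(Lz / bin_width))
    breaks <- seq(-Lz / 2, Lz / 2, length.out = nb + 1L)
  }
  breaks <- sort(breaks)
  z <- wrap_centered(traj$xyz[, ip, 3, drop = FALSE], Lz)
  if (min(z) < breaks[1] || max(z) > breaks[length(breaks)])
    stop("`breaks` must cover the box z-range")
  prof <- profile_from_z(as.numeric(z), breaks, water_region, temperature,
                         units)
  if (n_blocks >= 2L)
    prof$F_err <- block_errors(traj, bin_width = bin_width, breaks = breaks,
                               water_region = water_region,
                               temperature = temperature, units = units,
                               n_blocks = n_blocks)
  prof
}

# core: histogram -> Boltzmann inversion -> water-region shift
profile_from_z <- function(z, breaks, water_region, temperature, units) {
  stopifnot(length(water_region) == 2L, water_region[1] < water_region[2])
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(centers))
  p <- counts / sum(counts)
  Fv <- ifelse(counts > 0, -kBT(temperature) * log(p), NA_real_)
  in_water <- abs(centers) >= water_region[1] & abs(centers) <= water_region[2]
  if (!any(in_water & counts > 0))
    stop("water region [", water_region[1], ", ", water_region[2],
         "] angstrom contains no counts; cannot set the F = 0 reference")
  Fv <- Fv - mean(Fv[in_water & counts > 0])
  if (units == "kBT") Fv <- Fv / kBT(temperature)
  structure(list(bin_centers = centers, F = Fv,
                 F_err = rep(NA_real_, length(centers)),
                 counts = counts, breaks = breaks,
                 water_region = water_region, temperature = temperature,
                 units = units),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  ok <- !is.na(x$F)
  cat("<fe_profile> ", length(x$bin_centers), " bins (",
      sum(ok), " sampled), units ", x$units, ", T = ", x$temperature,
      " K\n", sep = "")
  cat("  water region: ", x$water_region[1], " <= |z| <= ",
      x$water_region[2], " A (F = 0 reference)\n", sep = "")
  if (any(ok))
    cat(sprintf("  F range: [%.3f, %.3f] %s\n",
                min(x$F[ok]), max(x$F[ok]), x$units))
  invisible(x)
}

#' Block-averaged errors for a free-energy profile
#'
#' Splits the trajectory into `n_blocks` contiguous, equal-length segments
#' (the trailing remainder is dropped), recomputes the shifted profile per
#' block, and reports the per-bin standard error of the block estimates,
#' `sd(blocks) / sqrt(n_available)`. Bins undefined in a block are excluded
#' pairwise; bins defined in fewer than two blocks get `NA`.
#'
#' @inheritParams free_energy_profile
#' @return numeric vector of per-bin standard errors, in `units`
#' @export
block_errors <- function(traj, bin_width = 0.5, breaks = NULL, water_region,
                         temperature = 310, units = c("kJ/mol", "kBT"),
                         n_blocks = 10) {
  stopifnot(is_trajectory(traj))
  units <- match.arg(units)
  if (n_blocks < 2L) stop("block averaging needs n_blocks >= 2")
  traj <- recenter_membrane(traj)
  ip <- particles_with_role(traj, "permeant")
  if (length(ip) == 0L) stop("trajectory has no permeant-labeled particles")
  Lz <- traj$box[1, 3]
  if (is.null(breaks)) {
    nb <- max(1L, ceiling(Lz / bin_width))
    breaks <- seq(-Lz / 2, Lz / 2, length.out = nb + 1L)
  }
  breaks <- sort(breaks)
  nf <- n_frames(traj)
  blen <- nf %/% n_blocks
  if (blen < 1L) stop("trajectory too short for ", n_blocks, " blocks")
  Fb <- matrix(NA_real_, nrow = n_blocks, ncol = length(breaks) - 1L)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * blen + 1L):(b * blen)
    z <- wrap_centered(traj$xyz[idx, ip, 3, drop = FALSE], Lz)
    pb <- profile_from_z(as.numeric(z), breaks, water_region, temperature,
                         units)
    Fb[b, ] <- pb$F
  }
  navail <- colSums(!is.na(Fb))
  err <- rep(NA_real_, ncol(Fb))
  ok <- navail >= 2L
  err[ok] <- apply(Fb[, ok, drop = FALSE], 2L, stats::sd, na.rm = TRUE) /
    sqrt(navail[ok])
  err
}

#' Membrane partitioning free energy from a profile
#'
#' Free-energy difference for the permeant between the water phase and the
#' membrane center, in units of kBT:
#' `dG_m = F(water) - F(z = 0) = -F(0)` (the water region is the F = 0
#' reference). Positive when the permeant prefers the membrane center.
#' `F(0)` is read from the bin containing z = 0.
#'
#' @param profile an `fe_profile`
#' @return `dG_m` in kBT units (a bare number)
#' @export
delta_g_membrane <- function(profile) {
  stopifnot(inherits(profile, "fe_profile"))
  i0 <- findInterval(0, profile$breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  F0 <- profile$F[i0]
  if (is.na(F0))
    stop("the bin containing z = 0 is empty; dG_m is undefined")
  if (profile$units == "kJ/mol") F0 <- F0 / kBT(profile$temperature)
  -F0
}
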