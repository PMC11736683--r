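#' Mean-square displacement with multiple time origins
#'
#' For each lag (a multiple of the frame interval up to `max_lag`), the MSD
#' is averaged over all permeant particles and all time origins, using
#' unwrapped coordinates. The squared displacement is summed over the
#' requested axes, so the free-diffusion law reads
#' `MSD(t) = 2 d D t` with `d` the dimensionality.
#'
#' @param traj a `memgas_traj` with unwrapped coordinates
#' @param max_lag largest lag in ps (default: a quarter of the time span)
#' @param dims axes to include: subset of `c("x", "y", "z")` (default all
#'   three; pass `"z"` for 1D trajectories)
#' @param lag_stride compute every `lag_stride`-th lag on the frame grid
#'   (default 1); thins the lag grid, not the origins
#' @return an `msd_curve` with `lags` (ps), `msd` (A^2), `n_origins`, and
#'   `dimensionality`
#' @examples
#' tr <- simulate_free_3d(D = 0.5, n_particles = 5, n_steps = 2000, seed = 2)
#' mc <- msd(tr, max_lag = 200)
#' @export
msd <- function(traj, max_lag = NULL, dims = c("x", "y", "z"),
                lag_stride = 1L) {
  stopifnot(is_trajectory(traj))
  if (is.null(traj$xyz_unwrapped))
    stop("MSD needs unwrapped coordinates; this trajectory stores only ",
         "wrapped positions. Re-run the generator (which stores both) or ",
         "unwrap the coordinate series before calling msd().")
  dims <- match.arg(dims, several.ok = TRUE)
  ax <- match(dims, c("x", "y", "z"))
  ip <- particles_with_role(traj, "permeant")
  if (length(ip) == 0L) ip <- seq_len(n_particles(traj))
  nf <- n_frames(traj)
  if (nf < 2L) stop("MSD undefined for single-frame trajectories")
  dt <- frame_interval(traj)
  span <- traj$times[nf] - traj$times[1]
  if (is.null(max_lag)) max_lag <- span / 4
  max_lag_frames <- min(nf - 1L, floor(max_lag / dt + 1e-9))
  if (max_lag_frames < 1L) stop("max_lag is below the frame interval")
  lag_frames <- seq(1L, max_lag_frames, by = as.integer(lag_stride))
  # [frame, particle*axis] matrix for fast columnwise differencing
  u <- traj$xyz_unwrapped[, ip, ax, drop = FALSE]
  u <- matrix(u, nrow = nf)
  msd_v <- numeric(length(lag_frames))
  n_origins <- integer(length(lag_frames))
  np <- length(ip)
  for (i in seq_along(lag_frames)) {
    l <- lag_frames[i]
    d <- u[(1L + l):nf, , drop = FALSE] - u[1L:(nf - l), , drop = FALSE]
    # sum squared displacement over axes, then average origins x particles
    sq <- d^2
    tot <- 0
    for (a in seq_along(ax))
      tot <- tot + sq[, ((a - 1L) * np + 1L):(a * np), drop = FALSE]
    msd_v[i] <- mean(tot)
    n_origins[i] <- nf - l
  }
  structure(list(lags = c(0, lag_frames * dt), msd = c(0, msd_v),
                 n_origins = c(nf, n_origins),
                 dimensionality = length(ax)),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat("<msd_curve> ", length(x$lags), " lags up to ",
      format(max(x$lags)), " ps, dimensionality ", x$dimensionality,
      "\n", sep = "")
  invisible(x)
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least-squares fit of MSD versus lag time restricted to a fit
#' window; `D = slope / (2 d)` with `d` the dimensionality. The reference
#' window for long production runs is 1-50 ns; when the curve is shorter
#' than that, the default window spans 5-25 percent of the largest lag.
#'
#' @param curve an `msd_curve`
#' @param window length-2 numeric fit window in ps; `NULL` for the default
#'   described above
#' @return a `diffusion_result` with `D_pbc` (A^2/ps), the window, and fit
#'   metadata; `D_corrected` is `NA` until [pbc_correct()] is applied
#' @examples
#' mc <- structure(list(lags = 0:100, msd = 6 * 0.714 * (0:100),
#'                      n_origins = rep(100L, 101L), dimensionality = 3L),
#'                 class = "msd_curve")
#' fit_diffusion(mc)$D_pbc  # 0.714
#' @export
fit_diffusion <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  lmax <- max(curve$lags)
  if (is.null(window)) {
    window <- if (lmax >= 50000) c(1000, 50000) else c(0.05, 0.25) * lmax
  }
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (window[1] > lmax)
    stop("fit window [", window[1], ", ", window[2],
         "] ps lies outside the lag range (max ", lmax, " ps)")
  sel <- curve$lags >= window[1] & curve$lags <= window[2]
  if (sum(sel) < 5L)
    stop("fit window contains ", sum(sel), " points; need at least 5")
  fit <- stats::lm(msd ~ lags,
                   data = data.frame(lags = curve$lags[sel],
                                     msd = curve$msd[sel]))
  slope <- unname(stats::coef(fit)[2])
  D <- slope / (2 * curve$dimensionality)
  structure(list(D_pbc = D, D_corrected = NA_real_, fit_window = window,
                 slope = slope, dimensionality = curve$dimensionality,
                 n_points = sum(sel), boundary_condition = NA_character_,
                 eta = NA_real_, L = NA_real_, radius = NA_real_,
                 correction_term = NA_real_),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("<diffusion_result>\n")
  cat(sprintf("  D_pbc = %.4g A^2/ps (fit window %.6g-%.6g ps, %dD, %d points)\n",
              x$D_pbc, x$fit_window[1], x$fit_window[2], x$dimensionality,
              x$n_points))
  if (!is.na(x$D_corrected))
    cat(sprintf("  D_corrected = %.4g A^2/ps (+%.3g; L = %.6g A, eta = %.3g Pa s, %s)\n",
                x$D_corrected, x$correction_term, x$L, x$eta,
                x$boundary_condition))
  invisible(x)
}

#' Hydrodynamic finite-size (periodic-boundary) correction
#'
#' Self-diffusion measured in a periodic box is suppressed by hydrodynamic
#' self-interaction across the images. The leading-order correction for a
#' cubic box is additive:
#' `D_corrected = D_pbc + kB T xi / (6 pi eta L)` with `xi = 2.837297`
#' (cubic-lattice self-term), `eta` the solvent shear viscosity, and `L`
#' the box edge. The boundary-condition flag (`"stick"` or `"slip"`) and
#' the hydrodynamic radius `R` are recorded as metadata; no higher-order
#' radius-dependent refinement is applied.
#'
#' @param result a `diffusion_result` from [fit_diffusion()]
#' @param temperature temperature in K
#' @param eta solvent shear viscosity in Pa s (required)
#' @param L cubic box edge length in angstrom
#' @param bc boundary condition label, `"stick"` or `"slip"` (metadata)
#' @param radius hydrodynamic radius of the permeant in angstrom (metadata)
#' @return the `diffusion_result` with `D_corrected` and
#'   `correction_term` (A^2/ps) filled in
#' @examples
#' res <- structure(list(D_pbc = 0.714, D_corrected = NA_real_,
#'                       fit_window = c(1000, 50000), slope = NA_real_,
#'                       dimensionality = 3L, n_points = 50L,
#'                       boundary_condition = NA_character_, eta = NA_real_,
#'                       L = NA_real_, radius = NA_real_,
#'                       correction_term = NA_real_),
#'                  class = "diffusion_result")
#' pbc_correct(res, temperature = 310, eta = 1e-3, L = 203)$correction_term
#' # ~3.18e-3 A^2/ps
#' @export
pbc_correct <- function(result, temperature, eta, L, bc = c("stick", "slip"),
                        radius = NA_real_) {
  stopifnot(inherits(result, "diffusion_result"))
  bc <- match.arg(bc)
  if (missing(eta) || is.null(eta) || is.na(eta))
    stop("the finite-size correction requires the solvent viscosity `eta` (Pa s)")
  stopifnot(temperature > 0, eta > 0, L > 0)
  term_m2s <- .memgas$kB_J * temperature * .memgas$xi_cubic /
    (6 * pi * eta * (L * 1e-10))
  term <- term_m2s * .memgas$m2_per_s_to_A2_per_ps
  result$D_corrected <- result$D_pbc + term
  result$correction_term <- term
  result$boundary_condition <- bc
  result$eta <- eta
  result$L <- L
  result$radius <- radius
  result
}
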