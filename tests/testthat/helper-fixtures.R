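# Small trajectory builders used across test files.

# 1D z-series for a single permeant (x = y = 0), nominal 1 A lateral box.
traj_from_z <- function(z, dt = 1, box_z = 10, label = "permeant",
                        unwrapped = FALSE) {
  nf <- length(z)
  xyz <- array(0, dim = c(nf, 1L, 3L))
  xyz[, 1, 3] <- z
  trajectory(times = dt * (seq_len(nf) - 1), xyz = xyz,
             box = c(1, 1, box_z), labels = label,
             xyz_unwrapped = if (unwrapped) xyz else NULL,
             periodic = c(FALSE, FALSE, TRUE))
}

# Multi-particle 3D trajectory from an array [frame, particle, axis].
traj_from_xyz <- function(xyz, dt = 1, box = c(100, 100, 100),
                          labels = "permeant", unwrapped = FALSE) {
  nf <- dim(xyz)[1]
  trajectory(times = dt * (seq_len(nf) - 1), xyz = xyz, box = box,
             labels = labels,
             xyz_unwrapped = if (unwrapped) xyz else NULL)
}

# Positions drawn bin-uniformly so the histogram is analytically known:
# bin probabilities `probs` over `breaks`.
z_from_bin_probs <- function(breaks, counts) {
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rep(centers, times = counts)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
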