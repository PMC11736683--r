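test_that("tabular dialect round-trips trajectories exactly", {
  # deterministic pseudo-random trajectory, wrapped + unwrapped
  set.seed(1)
  nf <- 100L; np <- 3L
  xyz <- array(runif(nf * np * 3, -25, 25), dim = c(nf, np, 3L))
  xyz_u <- xyz + array(rep(c(0, 50, -50), each = nf), dim = c(nf, np, 3L))
  tr <- trajectory(times = 20 * (seq_len(nf) - 1), xyz = xyz,
                   box = c(50, 50, 50),
                   labels = c("permeant", "phosphate", "cavity_residue:84LEU"),
                   xyz_unwrapped = xyz_u)
  f <- tempfile(fileext = ".traj")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$times, tr$times)
  expect_equal(back$labels, tr$labels)
  expect_equal(back$box, tr$box)
  expect_lt(max(abs(back$xyz - tr$xyz)), 1e-6)
  expect_lt(max(abs(back$xyz_unwrapped - tr$xyz_unwrapped)), 1e-6)

  # byte-stable across repeated writes
  f2 <- tempfile(fileext = ".traj")
  write_trajectory(tr, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("simple 3-frame file reads back identity values", {
  tr <- traj_from_z(c(0, 1, 2), dt = 20)
  f <- tempfile(fileext = ".traj")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$times, c(0, 20, 40))
  expect_equal(as.numeric(back$xyz[, 1, 3]), c(0, 1, 2))
  expect_equal(n_particles(back), 1L)
})

test_that("empty-particle trajectories survive a round trip", {
  tr <- trajectory(times = c(0, 10), xyz = array(numeric(0), c(2L, 0L, 3L)),
                   box = c(5, 5, 5), labels = character(0))
  f <- tempfile(fileext = ".traj")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(n_particles(back), 0L)
  expect_equal(n_frames(back), 2L)
})

test_that("constructor enforces the trajectory invariants", {
  xyz <- array(0, dim = c(3L, 1L, 3L))
  expect_error(trajectory(c(0, 1, 1.5), xyz, c(1, 1, 1), "permeant"),
               "uniform")
  expect_error(trajectory(c(0, -1, -2), xyz, c(1, 1, 1), "permeant"),
               "increasing")
  expect_error(trajectory(c(0, 1, 2), xyz, c(1, 0, 1), "permeant"),
               "box")
  bad <- xyz; bad[2, 1, 1] <- NaN
  expect_error(trajectory(c(0, 1, 2), bad, c(1, 1, 1), "permeant"),
               "finite")
  expect_error(trajectory(c(0, 1, 2), xyz, c(1, 1, 1),
                          c("permeant", "other")),
               "one role per particle")
})

test_that("role labels partition the particles", {
  xyz <- array(0, dim = c(2L, 5L, 3L))
  tr <- trajectory(c(0, 1), xyz, c(1, 1, 1),
                   c("permeant", "permeant", "phosphate",
                     "cavity_residue:28GLY", "other"))
  n_by_role <- length(particles_with_role(tr, "permeant")) +
    length(particles_with_role(tr, "phosphate")) +
    length(particles_with_role(tr, "cavity_residue")) +
    length(particles_with_role(tr, "other"))
  expect_equal(n_by_role, n_particles(tr))
})

test_that("generator save count matches the trajectory frame count", {
  sp <- permeation_spec(D = 0.5, box_z = 20, n_steps = 1e4, seed = 5,
                        save_every = 10)
  tr <- simulate_permeation_1d(sp)
  expect_equal(n_frames(tr), 1e4 / 10 + 1)
  expect_equal(frame_interval(tr), 10)  # dt * save_every
})

test_that("unreadable or malformed files give informative errors", {
  expect_error(read_trajectory(tempfile()), "not found")
  f <- tempfile()
  writeLines(c("not a trajectory", "at all"), f)
  expect_error(read_trajectory(f), "magic")
  # truncated body names the expectation
  tr <- traj_from_z(c(0, 1, 2), dt = 20)
  f2 <- tempfile(fileext = ".traj")
  write_trajectory(tr, f2)
  lines <- readLines(f2)
  writeLines(lines[-length(lines)], f2)
  expect_error(read_trajectory(f2), "rows")
})

test_that("membrane recentering shifts z by the phosphate midplane", {
  xyz <- array(0, dim = c(2L, 3L, 3L))
  xyz[, 1, 3] <- c(5, 7)    # phosphate
  xyz[, 2, 3] <- c(1, 1)    # phosphate
  xyz[, 3, 3] <- c(0, 0)    # permeant
  tr <- trajectory(c(0, 1), xyz, c(10, 10, 30),
                   c("phosphate", "phosphate", "permeant"))
  rc <- recenter_membrane(tr)
  expect_equal(as.numeric(rc$xyz[, 3, 3]), c(-3, -4))
})

test_that("multi-model PDB files read with role assignment", {
  pdb_lines <- c(
    "MODEL        1",
    "ATOM      1  O2  LIG A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  P   POP A   2       1.000   2.000  19.300  1.00  0.00           P",
    "ATOM      3  P   POP A   3       1.000   2.000 -19.300  1.00  0.00           P",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  O2  LIG A   1       0.500   0.000   1.000  1.00  0.00           O",
    "ATOM      2  P   POP A   2       1.000   2.000  19.300  1.00  0.00           P",
    "ATOM      3  P   POP A   3       1.000   2.000 -19.300  1.00  0.00           P",
    "ENDMDL",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines, f)
  tr <- read_trajectory(f, role_map = list(permeant = "^O2$",
                                           phosphate = "^P$"))
  expect_equal(n_frames(tr), 2L)
  expect_equal(tr$labels, c("permeant", "phosphate", "phosphate"))
  expect_equal(as.numeric(tr$xyz[2, 1, ]), c(0.5, 0, 1))
  # unlabeled particles default to "other"
  tr2 <- read_trajectory(f, role_map = list(permeant = "^O2$"))
  expect_equal(tr2$labels[2], "other")
  # and the dividing-surface pipeline runs off the labels
  expect_equal(dividing_surfaces(tr, offset = 8)$h2, 27.3)
})
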