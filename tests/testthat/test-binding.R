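cavity_traj <- function(bead_xyz, cavity_xyz, box = c(100, 100, 100),
                        residues = c("84LEU", "87VAL")) {
  # bead_xyz: [frame, 3]; cavity_xyz: list of [frame, 3] per residue particle
  nf <- nrow(bead_xyz)
  np <- 1L + length(cavity_xyz)
  xyz <- array(0, dim = c(nf, np, 3L))
  xyz[, 1, ] <- bead_xyz
  for (i in seq_along(cavity_xyz)) xyz[, i + 1L, ] <- cavity_xyz[[i]]
  labels <- c("permeant",
              paste0("cavity_residue:", residues[seq_along(cavity_xyz)]))
  trajectory(20 * (seq_len(nf) - 1), xyz, box, labels)
}

test_that("cavity distances use the center of geometry and minimum image", {
  cav <- cavity_spec("c", c("84LEU", "87VAL"), "hydrophobic")
  # two cavity particles at (+/-1, 0, 0): center at the origin
  tr <- cavity_traj(matrix(0, 1, 3),
                    list(matrix(c(1, 0, 0), 1), matrix(c(-1, 0, 0), 1)))
  expect_equal(as.numeric(cavity_distance_series(tr, cav)), 0)
  # bead at 6 A is exactly at the cutoff boundary -> bound under <=
  tr2 <- cavity_traj(matrix(c(6, 0, 0), 1),
                     list(matrix(c(1, 0, 0), 1), matrix(c(-1, 0, 0), 1)))
  d <- cavity_distance_series(tr2, cav)
  expect_equal(as.numeric(d), 6)
  expect_equal(nrow(detect_binding_events(d, cutoff = 6)), 1L)
  # bead across the periodic boundary: 99 vs center at 1, box 100 -> 2 A
  tr3 <- cavity_traj(matrix(c(99, 0, 0), 1),
                     list(matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1)))
  expect_equal(as.numeric(cavity_distance_series(tr3, cav)), 2)
  # missing residue labels are reported by name
  cav2 <- cavity_spec("c", c("84LEU", "99ALA"), "hydrophobic")
  expect_error(cavity_distance_series(tr, cav2), "99ALA")
})

test_that("event detection merges short gaps and keeps long ones", {
  # 5 bound frames at 20 ps -> one event of 100 ps
  d <- c(rep(1, 5), rep(9, 3))
  ev <- detect_binding_events(d, cutoff = 6, frame_interval = 20)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 100)
  expect_equal(ev$duration, ev$t_end - ev$t_start + 20)

  # runs {0-2} and {5-7}: 40 ps gap <= 60 ps -> merged into 160 ps
  d2 <- c(1, 1, 1, 9, 9, 1, 1, 1)
  ev2 <- detect_binding_events(d2)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$duration, 160)

  # 80 ps gap > 60 ps -> two events
  d3 <- c(1, 1, 1, 9, 9, 9, 9, 1, 1, 1)
  ev3 <- detect_binding_events(d3)
  expect_equal(nrow(ev3), 2L)
  expect_equal(ev3$duration, c(60, 60))

  # merge_gap below the frame interval is inert (warned)
  expect_warning(detect_binding_events(d2, merge_gap = 10), "no effect")
})

test_that("increasing merge_gap never increases n nor decreases mean residence", {
  set.seed(11)
  for (rep in 1:5) {
    d <- ifelse(runif(300) < 0.4, 1, 9)
    gaps <- c(0, 20, 40, 80, 160)
    res <- lapply(gaps, function(g)
      suppressWarnings(detect_binding_events(d, merge_gap = g)))
    n <- vapply(res, nrow, 1L)
    tbar <- vapply(res, function(e) mean(e$duration), numeric(1))
    expect_true(all(diff(n) <= 0))
    expect_true(all(diff(tbar) >= -1e-9))
  }
})

test_that("binding summaries reproduce the published residence arithmetic", {
  tab <- lysozyme_binding_table()
  s <- binding_summary(totals = tab[, c("cavity", "n", "t_ns")],
                       n_beads = 2, n_replicas = 29, production_ns = 2000)
  expect_equal(round(s$tbar_ns[s$cavity == "cavity 4"], 3), 0.625)
  expect_equal(round(s$tbar_ns[s$cavity == "cavity 3"], 3), 0.542)
  expect_equal(round(s$tbar_ns[s$cavity == "cavity 1"], 3), 0.263)
  expect_equal(round(s$occupancy_pct[s$cavity == "cavity 4"], 3), 1.475)
  expect_equal(round(s$occupancy_pct[s$cavity == "cavity 1"], 3), 0.064)
  # t = tbar * n exactly, for every cavity
  expect_equal(s$tbar_ns * s$n, s$t_ns, tolerance = 1e-12)
})

test_that("summaries built from events are self-consistent", {
  ev <- rbind(
    data.frame(cavity = "a", bead = 1, t_start = 0, t_end = 80,
               duration = 100),
    data.frame(cavity = "a", bead = 1, t_start = 200, t_end = 240,
               duration = 60),
    data.frame(cavity = "b", bead = 2, t_start = 0, t_end = 0,
               duration = 20))
  s <- binding_summary(events = ev, n_beads = 2, n_replicas = 1,
                       production_ns = 1)
  expect_equal(s$n, c(2L, 1L))
  expect_equal(s$t_ns, c(0.16, 0.02))
  expect_equal(s$tbar_ns * s$n, s$t_ns, tolerance = 1e-12)
  # single event: tbar = duration, se undefined
  expect_equal(s$tbar_ns[2], 0.02)
  expect_true(is.na(s$tbar_se_ns[2]))
  # occupancy: 0.16 ns over 2 beads x 1 ns = 8%
  expect_equal(s$occupancy_pct[1], 8)
})

test_that("binding free energy follows the density-ratio law", {
  # rho_cavity = rho_water -> 0
  v <- 4 / 3 * pi * 6^3
  occ <- 0.05
  expect_equal(binding_free_energy(occ, cutoff = 6, rho_water = occ / v,
                                   form = "number"), 0, tolerance = 1e-12)
  # published occupancies with rho_water = 0.283 kg/m^3, m = 32, T = 310
  dF4 <- binding_free_energy(1710.50 / (2 * 29 * 2000), rho_water = 0.283)
  expect_lt(abs(dF4 - (-2.83)), 0.1)
  dF1 <- binding_free_energy(74.56 / (2 * 29 * 2000), rho_water = 0.283)
  expect_lt(abs(dF1 - 5.26), 0.1)
  # zero occupancy flags an unbounded free energy
  expect_warning(res <- binding_free_energy(0, rho_water = 0.283),
                 "zero occupancy")
  expect_identical(res, Inf)
})

test_that("water-phase density arithmetic converts units correctly", {
  # one bead always outside, box 100^3 A^3, m = 32 g/mol
  tr <- traj_from_xyz(array(40, dim = c(3, 1, 3)))
  rho <- water_phase_density(tr)
  expect_equal(rho, 32e-3 / 6.02214076e23 / 1e-24, tolerance = 1e-9)
  expect_equal(rho, 0.0531, tolerance = 1e-3)
  # with a cavity sphere excluded, a bead inside it does not count
  excl <- data.frame(x = 40, y = 40, z = 40, radius = 6)
  expect_equal(water_phase_density(tr, exclusion = excl), 0)
  # no beads -> zero density
  tr0 <- traj_from_xyz(array(0, dim = c(2, 1, 3)), labels = "other")
  expect_equal(water_phase_density(tr0), 0)
})

test_that("density maps conserve counts and localize a static bead", {
  tr <- traj_from_xyz(array(rep(c(10.2, -20.4, 30.6), each = 5),
                            dim = c(5, 1, 3)))
  dm <- density_map(tr, voxel = 1)
  expect_equal(sum(dm$counts), 5)
  expect_equal(sum(dm$counts == 5), 1L)  # all counts in one voxel
  expect_equal(dm$normalization, 5)
  # a deep well attracts the densest voxel to the well center
  wells <- data.frame(x = 5, y = -5, z = 5, radius = 4, depth = 15)
  bs <- binding_spec(box = 30, wells = wells, step_size = 3, n_steps = 3e4,
                     seed = 4)
  tb <- simulate_binding_3d(bs)
  dmb <- density_map(tb, voxel = 1.5)
  i <- which(dmb$counts == max(dmb$counts), arr.ind = TRUE)[1, ]
  center <- dmb$origin + (i - 0.5) * dmb$voxel
  expect_lt(sqrt(sum((center - c(5, -5, 5))^2)), 4)
})

test_that("OpenDX output is well-formed and complete", {
  tr <- traj_from_xyz(array(runif(30, -10, 10), dim = c(5, 2, 3)),
                      box = c(20, 20, 20))
  dm <- density_map(tr, voxel = 2)
  f <- tempfile(fileext = ".dx")
  write_opendx(dm, f)
  lines <- readLines(f)
  expect_true(any(grepl("gridpositions counts 10 10 10", lines)))
  body <- lines[grep("data follows", lines) + 1:(ceiling(1000 / 3))]
  vals <- as.numeric(unlist(strsplit(paste(body, collapse = " "), " +")))
  expect_equal(sum(vals), 10)  # frames x particles
})

test_that("packaged cavity definitions match the benchmark layout", {
  cavs <- lysozyme_cavities()
  expect_length(cavs, 5L)
  expect_equal(cavs[["cavity 4"]]$class, "hydrophobic")
  expect_length(cavs[["cavity 4"]]$residues, 8L)
  expect_true("84LEU" %in% cavs[["cavity 4"]]$residues)
  expect_equal(cavs[["cavity 5"]]$class, "random")
  expect_length(cavs[["cavity 5"]]$residues, 10L)
  expect_equal(vapply(cavs, function(c) c$cutoff, numeric(1)),
               rep(6, 5), ignore_attr = TRUE)
})

test_that("disjoint-cavity occupancies are subadditive per bead", {
  # one bead alternating among two disjoint regions and free space
  set.seed(5)
  nf <- 200L
  pos <- matrix(runif(nf * 3, -15, 15), ncol = 3)
  tr <- traj_from_xyz(array(pos, dim = c(nf, 1, 3)), box = c(30, 30, 30))
  cavA <- data.frame(x = 5, y = 5, z = 5, radius = 4)
  cavB <- data.frame(x = -8, y = -8, z = -8, radius = 4)
  inA <- sqrt(rowSums(sweep(pos, 2, unlist(cavA[1, 1:3]))^2)) <= 4
  inB <- sqrt(rowSums(sweep(pos, 2, unlist(cavB[1, 1:3]))^2)) <= 4
  occA <- 100 * mean(inA); occB <- 100 * mean(inB)
  expect_lte(occA + occB, 100)
  expect_equal(sum(inA & inB), 0L)  # disjoint spheres never double-count
})
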