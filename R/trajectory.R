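#' Particle trajectory container
#'
#' A `memgas_traj` holds time-ordered particle coordinates with an
#' orthorhombic periodic box and a role label per particle. It is the common
#' currency of all analysis stages: the membrane normal is the z axis and,
#' for membrane systems, z = 0 is the bilayer midplane.
#'
#' Internally: `times` is a uniform grid in ps; `xyz` (and optionally
#' `xyz_unwrapped`) is an array `[frame, particle, axis]` in angstrom;
#' `box` is an `n_frames x 3` matrix of edge lengths in angstrom; `labels`
#' is one role per particle, one of `"permeant"`, `"phosphate"`,
#' `"solvent"`, `"other"`, or `"cavity_residue:<name>"`.
#'
#' @param times numeric vector of frame times (ps), strictly increasing with
#'   constant spacing
#' @param xyz numeric array `[n_frames, n_particles, 3]` of wrapped
#'   coordinates (angstrom)
#' @param box numeric length-3 vector or `n_frames x 3` matrix of box edge
#'   lengths (angstrom)
#' @param labels character vector of per-particle roles (recycled if length
#'   1); unknown roles are kept verbatim so user-defined tags survive I/O
#' @param xyz_unwrapped optional array like `xyz` with unwrapped coordinates
#' @param periodic logical length-3: periodicity per axis
#' @return an object of class `memgas_traj`
#' @examples
#' z <- c(0, 1, 2)
#' tr <- trajectory(times = c(0, 20, 40),
#'                  xyz = array(c(0, 0, 0, 0, 0, 0, z), dim = c(3, 1, 3)),
#'                  box = c(10, 10, 10), labels = "permeant")
#' n_frames(tr)
#' @export
trajectory <- function(times, xyz, box, labels = "other",
                       xyz_unwrapped = NULL, periodic = c(TRUE, TRUE, TRUE)) {
  times <- as.numeric(times)
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  stopifnot(is.array(xyz), length(dim(xyz)) == 3L, dim(xyz)[3] == 3L)
  nf <- dim(xyz)[1]
  np <- dim(xyz)[2]
  if (length(times) != nf)
    stop("`times` length (", length(times), ") does not match frame count (",
         nf, ")")
  if (nf >= 2L) {
    if (any(diff(times) <= 0))
      stop("trajectory times must be strictly increasing")
    # compare against the ideal affine grid, relative to the full span,
    # so representation error in long time series does not trip the check
    ideal <- times[1] +
      (times[nf] - times[1]) / (nf - 1) * (seq_len(nf) - 1)
    if (max(abs(times - ideal)) > 1e-9 * (times[nf] - times[1]))
      stop("trajectory times must lie on a uniform grid ",
           "(non-uniform spacing detected)")
  }
  if (is.null(dim(box))) {
    stopifnot(length(box) == 3L)
    box <- matrix(as.numeric(box), nrow = nf, ncol = 3L, byrow = TRUE)
  } else {
    box <- as.matrix(box)
    stopifnot(nrow(box) == nf, ncol(box) == 3L)
  }
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box edge lengths must be finite and > 0 in all frames")
  if (np > 0 && any(!is.finite(xyz)))
    stop("all coordinates must be finite")
  labels <- as.character(labels)
  if (np > 0L) {
    if (length(labels) == 1L) labels <- rep(labels, np)
    if (length(labels) != np)
      stop("`labels` must have one role per particle")
    if (any(is.na(labels) | labels == "" | grepl("[[:space:]]", labels)))
      stop("role labels must be non-empty and contain no whitespace")
  } else {
    labels <- character(0)
  }
  if (!is.null(xyz_unwrapped)) {
    if (is.matrix(xyz_unwrapped))
      xyz_unwrapped <- array(xyz_unwrapped, dim = c(dim(xyz_unwrapped), 1L))
    stopifnot(identical(dim(xyz_unwrapped), dim(xyz)))
    if (np > 0 && any(!is.finite(xyz_unwrapped)))
      stop("all unwrapped coordinates must be finite")
  }
  stopifnot(is.logical(periodic), length(periodic) == 3L)
  structure(
    list(times = times, xyz = xyz, box = box, labels = labels,
         xyz_unwrapped = xyz_unwrapped, periodic = periodic),
    class = "memgas_traj"
  )
}

#' @rdname trajectory
#' @param x object to test or print
#' @export
is_trajectory <- function(x) inherits(x, "memgas_traj")

#' @export
print.memgas_traj <- function(x, ...) {
  nf <- n_frames(x)
  np <- n_particles(x)
  cat("<memgas_traj> ", nf, " frame", if (nf != 1) "s", ", ", np,
      " particle", if (np != 1) "s", "\n", sep = "")
  if (nf >= 2L)
    cat("  dt = ", format(frame_interval(x)), " ps, span = ",
        format(x$times[nf] - x$times[1]), " ps\n", sep = "")
  cat("  box (frame 1): ", paste(format(x$box[1, ]), collapse = " x "),
      " A\n", sep = "")
  if (np > 0L) {
    tab <- table(x$labels)
    cat("  roles: ", paste(names(tab), tab, sep = ":", collapse = ", "),
        "\n", sep = "")
  }
  cat("  unwrapped coordinates: ",
      if (is.null(x$xyz_unwrapped)) "no" else "yes", "\n", sep = "")
  invisible(x)
}

#' Trajectory accessors
#'
#' @param traj a `memgas_traj`
#' @return `n_frames()`/`n_particles()`: integer counts.
#'   `frame_interval()`: frame spacing in ps (NA for single-frame
#'   trajectories). `particles_with_role()`: integer indices of particles
#'   whose label equals `role` (or, for `"cavity_residue"`, starts with it).
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$xyz)[2]

#' @rdname n_frames
#' @export
frame_interval <- function(traj) {
  if (n_frames(traj) < 2L) return(NA_real_)
  (traj$times[n_frames(traj)] - traj$times[1]) / (n_frames(traj) - 1L)
}

#' @rdname n_frames
#' @param role a role label; `"cavity_residue"` matches any
#'   `"cavity_residue:<name>"` tag
#' @export
particles_with_role <- function(traj, role) {
  if (role == "cavity_residue")
    which(startsWith(traj$labels, "cavity_residue"))
  else
    which(traj$labels == role)
}

#' Recenter the membrane midplane to z = 0
#'
#' Subtracts, frame by frame, the mean z of the phosphate-labeled particles
#' from every particle's z coordinate, so the bilayer midplane sits at
#' z = 0. Trajectories from the synthetic generators are already centered
#' and carry no phosphate labels; those are returned unchanged.
#'
#' @param traj a `memgas_traj`
#' @return a `memgas_traj` with shifted z coordinates
#' @export
recenter_membrane <- function(traj) {
  ip <- particles_with_role(traj, "phosphate")
  if (length(ip) == 0L) return(traj)
  zp <- traj$xyz[, ip, 3, drop = FALSE]
  mid <- rowMeans(array(zp, dim = dim(zp)[1:2]))
  traj$xyz[, , 3] <- traj$xyz[, , 3] - mid
  if (!is.null(traj$xyz_unwrapped))
    traj$xyz_unwrapped[, , 3] <- traj$xyz_unwrapped[, , 3] - mid
  traj
}

# wrap coordinates into [-L/2, L/2) per axis
wrap_centered <- function(x, L) {
  x - L * floor(x / L + 0.5)
}

# --- tabular trajectory dialect ------------------------------------------

DIALECT_MAGIC <- "# memgas trajectory v1"

#' Read a trajectory
#'
#' Reads the package's plain-text tabular trajectory dialect, or (when the
#' optional bio3d package is installed) multi-model PDB files and DCD
#' coordinate series with a PDB topology.
#'
#' The tabular dialect is one magic comment line, one header line
#' (`n_particles`, `n_frames`, `dt_ps`, `t0_ps`, `box`, `periodic`,
#' `unwrapped` as `key=value` pairs), then one whitespace-separated row per
#' frame per particle: `frame id role x y z [ux uy uz]`.
#'
#' @param path file to read
#' @param topology optional PDB file providing atom metadata for DCD input
#' @param role_map optional named list mapping a role to a character vector
#'   of atom/residue name patterns (regular expressions), used to assign
#'   roles when reading structure formats; unmatched particles get role
#'   `"other"`. Example: `list(permeant = "^O2", phosphate = "^PO4?$")`.
#' @return a `memgas_traj`
#' @seealso [write_trajectory()]
#' @export
read_trajectory <- function(path, topology = NULL, role_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return(read_traj_pdb(path, role_map))
  if (ext == "dcd") return(read_traj_dcd(path, topology, role_map))
  read_traj_dialect(path)
}

read_traj_dialect <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, DIALECT_MAGIC))
    stop("not a memgas tabular trajectory (bad magic line): ", path)
  header <- readLines(con, n = 1L)
  kv <- strsplit(strsplit(trimws(header), "[[:space:]]+")[[1]], "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  h <- as.list(stats::setNames(vals, keys))
  need <- c("n_particles", "n_frames", "dt_ps", "t0_ps", "box", "periodic",
            "unwrapped")
  if (!all(need %in% names(h)))
    stop("trajectory header is missing fields: ",
         paste(setdiff(need, names(h)), collapse = ", "))
  np <- as.integer(h$n_particles)
  nf <- as.integer(h$n_frames)
  box <- as.numeric(strsplit(h$box, ",", fixed = TRUE)[[1]])
  periodic <- as.numeric(strsplit(h$periodic, ",", fixed = TRUE)[[1]]) != 0
  has_unwrapped <- h$unwrapped == "1"
  dt <- as.numeric(h$dt_ps)
  t0 <- as.numeric(h$t0_ps)
  times <- t0 + dt * seq(0, length.out = nf)
  if (np == 0L) {
    return(trajectory(times, array(numeric(0), dim = c(nf, 0L, 3L)), box,
                      character(0), periodic = periodic))
  }
  ncol_expect <- if (has_unwrapped) 9L else 6L
  tab <- utils::read.table(con, header = FALSE,
                           colClasses = c("integer", "integer", "character",
                                          rep("numeric", ncol_expect - 3L)),
                           col.names = c("frame", "id", "role", "x", "y", "z",
                                         if (has_unwrapped) c("ux", "uy", "uz")))
  if (nrow(tab) != nf * np)
    stop("trajectory body has ", nrow(tab), " rows; expected ", nf * np,
         " (frame ", tab$frame[nrow(tab)], " may be truncated)")
  # rows are frame-major, particle-minor; enforce instead of assuming
  ord <- order(tab$frame, tab$id)
  tab <- tab[ord, , drop = FALSE]
  labels <- tab$role[seq_len(np)]
  xyz <- array(NA_real_, dim = c(nf, np, 3L))
  xyz[, , 1] <- matrix(tab$x, nrow = nf, byrow = TRUE)
  xyz[, , 2] <- matrix(tab$y, nrow = nf, byrow = TRUE)
  xyz[, , 3] <- matrix(tab$z, nrow = nf, byrow = TRUE)
  xyz_u <- NULL
  if (has_unwrapped) {
    xyz_u <- array(NA_real_, dim = c(nf, np, 3L))
    xyz_u[, , 1] <- matrix(tab$ux, nrow = nf, byrow = TRUE)
    xyz_u[, , 2] <- matrix(tab$uy, nrow = nf, byrow = TRUE)
    xyz_u[, , 3] <- matrix(tab$uz, nrow = nf, byrow = TRUE)
  }
  trajectory(times, xyz, box, labels, xyz_unwrapped = xyz_u,
             periodic = periodic)
}

#' Write a trajectory in the tabular dialect
#'
#' Plain-text, deterministic output (coordinates printed with six decimals,
#' so round-trips reproduce coordinates to 1e-6 angstrom and repeated writes
#' are byte-identical). Requires a constant box across frames.
#'
#' @param traj a `memgas_traj`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is_trajectory(traj))
  if (n_frames(traj) > 1L &&
      any(abs(sweep(traj$box, 2L, traj$box[1, ])) > 1e-9))
    stop("the tabular dialect stores a single box; ",
         "this trajectory has a varying box")
  nf <- n_frames(traj)
  np <- n_particles(traj)
  dt <- frame_interval(traj)
  if (is.na(dt)) dt <- 0
  has_u <- !is.null(traj$xyz_unwrapped)
  header <- sprintf(
    "n_particles=%d n_frames=%d dt_ps=%s t0_ps=%s box=%s periodic=%s unwrapped=%d",
    np, nf, sprintf("%.15g", dt), sprintf("%.15g", traj$times[1]),
    paste(sprintf("%.15g", traj$box[1, ]), collapse = ","),
    paste(as.integer(traj$periodic), collapse = ","), as.integer(has_u))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(DIALECT_MAGIC, header), con)
  if (np == 0L) return(invisible(path))
  frame_col <- rep(seq_len(nf) - 1L, each = np)
  id_col <- rep(seq_len(np), times = nf)
  role_col <- rep(traj$labels, times = nf)
  fmt <- function(a) sprintf("%.6f", t(matrix(a, nrow = nf)))
  cols <- list(frame_col, id_col, role_col,
               fmt(traj$xyz[, , 1]), fmt(traj$xyz[, , 2]), fmt(traj$xyz[, , 3]))
  if (has_u)
    cols <- c(cols, list(fmt(traj$xyz_unwrapped[, , 1]),
                         fmt(traj$xyz_unwrapped[, , 2]),
                         fmt(traj$xyz_unwrapped[, , 3])))
  writeLines(do.call(paste, cols), con)
  invisible(path)
}

# --- structure-format readers (bio3d-backed) ------------------------------

assign_roles <- function(atom_names, res_names, res_ids, role_map) {
  np <- length(atom_names)
  labels <- rep("other", np)
  if (is.null(role_map)) return(labels)
  for (role in names(role_map)) {
    pats <- role_map[[role]]
    hit <- rep(FALSE, np)
    for (p in pats)
      hit <- hit | grepl(p, atom_names) | grepl(p, res_names)
    if (startsWith(role, "cavity_residue")) {
      labels[hit] <- paste0("cavity_residue:", res_ids[hit], res_names[hit])
    } else {
      labels[hit] <- role
    }
  }
  labels
}

need_bio3d <- function() {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading structure formats requires the `bio3d` package")
}

read_traj_pdb <- function(path, role_map) {
  need_bio3d()
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz_mat <- pdb$xyz                      # n_models x 3N
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1L)
  nf <- nrow(xyz_mat)
  np <- ncol(xyz_mat) / 3L
  xyz <- array(NA_real_, dim = c(nf, np, 3L))
  xyz[, , 1] <- xyz_mat[, seq(1L, by = 3L, length.out = np), drop = FALSE]
  xyz[, , 2] <- xyz_mat[, seq(2L, by = 3L, length.out = np), drop = FALSE]
  xyz[, , 3] <- xyz_mat[, seq(3L, by = 3L, length.out = np), drop = FALSE]
  labels <- assign_roles(pdb$atom$elety, pdb$atom$resid, pdb$atom$resno,
                         role_map)
  ranges <- apply(xyz, 3, function(m) diff(range(m)))
  box <- pmax(ranges, 1) + 2   # PDB carries no box; bounding estimate
  trajectory(seq(0, length.out = nf), xyz, box, labels,
             periodic = c(FALSE, FALSE, FALSE))
}

read_traj_dcd <- function(path, topology, role_map) {
  need_bio3d()
  if (is.null(topology))
    stop("reading DCD requires a PDB `topology` for particle roles")
  pdb <- bio3d::read.pdb(topology)
  xyz_mat <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz_mat)
  np <- ncol(xyz_mat) / 3L
  xyz <- array(NA_real_, dim = c(nf, np, 3L))
  xyz[, , 1] <- xyz_mat[, seq(1L, by = 3L, length.out = np), drop = FALSE]
  xyz[, , 2] <- xyz_mat[, seq(2L, by = 3L, length.out = np), drop = FALSE]
  xyz[, , 3] <- xyz_mat[, seq(3L, by = 3L, length.out = np), drop = FALSE]
  labels <- assign_roles(pdb$atom$elety, pdb$atom$resid, pdb$atom$resno,
                         role_map)
  ranges <- apply(xyz, 3, function(m) diff(range(m)))
  box <- pmax(ranges, 1) + 2
  trajectory(seq(0, length.out = nf), xyz, box, labels,
             periodic = c(TRUE, TRUE, TRUE))
}
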