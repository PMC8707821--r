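#' Heme tilt angle of one frame
#'
#' Angle between the heme plane, defined as the best-fit plane through the
#' four porphyrin nitrogens, and the membrane normal (the z-axis). The
#' plane normal is the smallest principal direction of the centered
#' coordinates (exact for coplanar atoms); the tilt is
#' `90 deg - angle(normal, z)`, folded into \[0, 90\]. A heme lying flat in
#' the membrane plane (nitrogens in a z = const plane) therefore reads 90
#' degrees, a heme plane containing the z-axis reads 0.
#'
#' @param coords 4 x 3 matrix of porphyrin-nitrogen coordinates (Å).
#' @param convention `"plane"` (default; plane vs z-axis, the convention
#'   matching the experimental 38-78 degree range) or `"normal"` (angle
#'   between the plane normal and z, the complement).
#' @return Angle in degrees in \[0, 90\].
#' @export
heme_tilt_angle <- function(coords, convention = c("plane", "normal")) {
  convention <- match.arg(convention)
  stopifnot(is.matrix(coords), nrow(coords) == 4, ncol(coords) == 3)
  centered <- sweep(coords, 2, colMeans(coords))
  sv <- svd(centered)
  # degenerate: collinear (or coincident) points leave the plane undefined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    stop("porphyrin nitrogens are collinear; heme plane undefined",
         call. = FALSE)
  }
  normal <- sv$v[, 3]
  cosang <- abs(normal[3]) / sqrt(sum(normal^2))
  ang_normal_z <- acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
  if (convention == "plane") 90 - ang_normal_z else ang_normal_z
}

#' Per-frame heme tilt series of a trajectory
#'
#' @param traj a `labeled_trajectory` with exactly 4 `PORPHYRIN_N` atoms.
#' @param convention see [heme_tilt_angle()].
#' @return A `metric_series` with per-frame angles (degrees), mean and sd.
#' @export
tilt_series <- function(traj, convention = "plane") {
  idx <- role_indices(traj$system, "PORPHYRIN_N")
  if (length(idx) != 4) {
    stop("expected exactly 4 PORPHYRIN_N atoms, found ", length(idx),
         call. = FALSE)
  }
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    heme_tilt_angle(frame_coords(traj, f, idx), convention)
  }, numeric(1))
  metric_series(v, frame_times(traj), "heme_tilt_deg")
}

#' Burying depth of one frame
#'
#' Separation along the membrane normal (z) between the unweighted centroid
#' of the protein alpha-carbons and the centroid of the lipid C1 carbons.
#' The z-projection is used rather than the 3D centroid distance because
#' the metric is defined relative to the membrane plane; a lateral offset
#' of the leaflet centroid would contaminate a 3D distance. The 3D variant
#' is available for comparison.
#'
#' @param ca_coords N x 3 matrix of alpha-carbon coordinates (Å).
#' @param c1_coords M x 3 matrix of lipid C1 coordinates (Å).
#' @param mode `"z"` (default) or `"3d"`.
#' @return Depth in Å (non-negative).
#' @export
burying_depth <- function(ca_coords, c1_coords, mode = c("z", "3d")) {
  mode <- match.arg(mode)
  if (NROW(ca_coords) == 0 || NROW(c1_coords) == 0) {
    stop("empty atom selection for burying depth", call. = FALSE)
  }
  ca <- colMeans(ca_coords)
  c1 <- colMeans(c1_coords)
  if (mode == "z") abs(ca[3] - c1[3]) else sqrt(sum((ca - c1)^2))
}

#' Per-frame burying-depth series of a trajectory
#'
#' @param traj a `labeled_trajectory` with `PROTEIN_CA` and `LIPID_C1` atoms.
#' @param mode see [burying_depth()].
#' @return A `metric_series` with per-frame depths (Å), mean and sd.
#' @export
depth_series <- function(traj, mode = "z") {
  ica <- role_indices(traj$system, "PROTEIN_CA")
  ic1 <- role_indices(traj$system, "LIPID_C1")
  if (length(ica) == 0 || length(ic1) == 0) {
    stop("need PROTEIN_CA and LIPID_C1 atoms for burying depth", call. = FALSE)
  }
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    burying_depth(frame_coords(traj, f, ica), frame_coords(traj, f, ic1), mode)
  }, numeric(1))
  metric_series(v, frame_times(traj), "burying_depth_A")
}

#' Radius of gyration of a selection
#'
#' Unweighted root-mean-square distance of the selected atoms from their
#' centroid, the standard compactness measure computed over alpha-carbons.
#'
#' @param coords N x 3 coordinate matrix (Å).
#' @return Rg in Å; 0 iff all atoms coincide.
#' @export
radius_of_gyration <- function(coords) {
  if (NROW(coords) == 0) stop("empty selection for Rg", call. = FALSE)
  coords <- matrix(coords, ncol = 3)
  centered <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(centered^2)))
}

#' Per-frame radius-of-gyration series (alpha-carbons)
#'
#' @param traj a `labeled_trajectory`.
#' @param role atom role to use, default `PROTEIN_CA`.
#' @return A `metric_series` with per-frame Rg (Å).
#' @export
gyration_series <- function(traj, role = "PROTEIN_CA") {
  idx <- role_indices(traj$system, role)
  if (length(idx) == 0) stop("no atoms with role ", role, call. = FALSE)
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(frame_coords(traj, f, idx))
  }, numeric(1))
  metric_series(v, frame_times(traj), "rg_A")
}

#' RMSD between a frame and a reference
#'
#' Optionally performs a least-squares rigid-body superposition (optimal
#' rotation plus translation) before computing the root-mean-square
#' deviation, so a rigidly moved copy reads 0.
#'
#' @param coords,reference N x 3 coordinate matrices (Å), matching rows.
#' @param superpose superpose before measuring, default `TRUE`.
#' @return RMSD in Å.
#' @export
rmsd_to_reference <- function(coords, reference, superpose = TRUE) {
  if (NROW(coords) != NROW(reference)) {
    stop("atom-count mismatch between frame and reference", call. = FALSE)
  }
  a <- as.numeric(t(coords))
  b <- as.numeric(t(reference))
  bio3d::rmsd(b, a, fit = superpose)
}

#' Per-frame RMSD series of a trajectory
#'
#' @param traj a `labeled_trajectory`.
#' @param role selection role, default `PROTEIN_CA`.
#' @param reference_frame frame used as reference, default 1.
#' @param superpose least-squares fit before each measurement.
#' @return A `metric_series` with per-frame RMSD (Å).
#' @export
rmsd_series <- function(traj, role = "PROTEIN_CA", reference_frame = 1,
                        superpose = TRUE) {
  idx <- role_indices(traj$system, role)
  if (length(idx) == 0) stop("no atoms with role ", role, call. = FALSE)
  ref <- frame_coords(traj, reference_frame, idx)
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    rmsd_to_reference(frame_coords(traj, f, idx), ref, superpose)
  }, numeric(1))
  metric_series(v, frame_times(traj), "rmsd_A")
}

#' Per-residue RMSF profile
#'
#' Superposes every frame onto the first over the selection, then measures
#' the root-mean-square fluctuation of each atom about the superposed
#' trajectory mean structure.
#'
#' @param traj a `labeled_trajectory`.
#' @param role selection role, default `PROTEIN_CA`.
#' @return Data frame with `residue_number` and `rmsf` (Å).
#' @export
rmsf_profile <- function(traj, role = "PROTEIN_CA") {
  idx <- role_indices(traj$system, role)
  if (length(idx) == 0) stop("no atoms with role ", role, call. = FALSE)
  xyz_idx <- as.vector(t(cbind(3 * idx - 2, 3 * idx - 1, 3 * idx)))
  sub <- traj$xyz[, xyz_idx, drop = FALSE]
  if (nrow(sub) > 1) {
    inds <- seq_len(ncol(sub))
    sub <- bio3d::fit.xyz(fixed = sub[1, ], mobile = sub,
                          fixed.inds = inds, mobile.inds = inds)
  }
  mean_str <- colMeans(sub)
  dev2 <- sweep(sub, 2, mean_str)^2
  # per-atom msf = mean over frames of |r - rbar|^2, summed over x,y,z
  msf <- rowSums(matrix(colMeans(dev2), ncol = 3, byrow = TRUE))
  data.frame(residue_number = traj$system$residue_number[idx],
             rmsf = sqrt(msf))
}

#' Construct a per-frame metric series
#'
#' @param values per-frame values.
#' @param times_ps frame times (ps).
#' @param metric metric name.
#' @return A `metric_series` list with `values`, `times_ps`, `metric`,
#'   `mean`, `sd`, `n`.
#' @export
metric_series <- function(values, times_ps = seq_along(values) - 1,
                          metric = "metric") {
  structure(list(values = values, times_ps = times_ps, metric = metric,
                 mean = mean(values), sd = stats::sd(values),
                 n = length(values)),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(x$metric, ": n =", x$n, ", mean =", signif(x$mean, 4),
      ", sd =", signif(x$sd, 4), "\n")
  invisible(x)
}

#' Validate membrane-model metrics against experimental ranges
#'
#' Checks the mean heme tilt angle against the rotational-diffusion range
#' 38-78 degrees and the mean burying depth against the atomic-force
#' microscopy value 35 +/- 9 Å (i.e. 26-44 Å). Bounds are inclusive.
#'
#' @param tilt a `metric_series` of tilt angles (degrees).
#' @param depth a `metric_series` of burying depths (Å).
#' @param tilt_range inclusive experimental tilt bounds (degrees).
#' @param depth_range inclusive experimental depth bounds (Å).
#' @return Data frame with one row per metric: `metric`, `mean`, `lower`,
#'   `upper`, `pass`.
#' @export
validate_membrane_model <- function(tilt, depth,
                                    tilt_range = c(38, 78),
                                    depth_range = c(26, 44)) {
  stopifnot(tilt$n > 0, depth$n > 0)
  data.frame(
    metric = c("heme_tilt_deg", "burying_depth_A"),
    mean = c(tilt$mean, depth$mean),
    lower = c(tilt_range[1], depth_range[1]),
    upper = c(tilt_range[2], depth_range[2]),
    pass = c(tilt$mean >= tilt_range[1] & tilt$mean <= tilt_range[2],
             depth$mean >= depth_range[1] & depth$mean <= depth_range[2])
  )
}
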