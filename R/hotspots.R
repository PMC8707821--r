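#' Per-residue ligand-association scores
#'
#' For each MD frame, counts the ligand heavy atoms within `cutoff` of each
#' protein alpha-carbon, accumulates the counts over frames, and normalizes
#' by the total number of ligand heavy atoms in the system (all ligand
#' copies pooled). The result quantifies how strongly small molecules
#' associate with each surface residue.
#'
#' @param traj a `labeled_trajectory` with `PROTEIN_CA` and `LIGAND_HEAVY`
#'   atoms.
#' @param cutoff contact distance in Å, default 5.
#' @return An `association_profile` data frame with `residue_number` and
#'   `score`, plus attributes `cutoff`, `n_frames`, `n_ligand_heavy`.
#' @export
association_scores <- function(traj, cutoff = 5) {
  ica <- role_indices(traj$system, "PROTEIN_CA")
  ilig <- role_indices(traj$system, "LIGAND_HEAVY")
  if (length(ica) == 0) stop("no PROTEIN_CA atoms", call. = FALSE)
  if (length(ilig) == 0) stop("no LIGAND_HEAVY atoms", call. = FALSE)
  nlig <- length(ilig)
  counts <- numeric(length(ica))
  cut2 <- cutoff^2
  for (f in seq_len(n_frames(traj))) {
    ca <- frame_coords(traj, f, ica)
    lig <- frame_coords(traj, f, ilig)
    # squared cross-distance matrix (residues x ligand atoms)
    d2 <- outer(rowSums(ca^2), rowSums(lig^2), "+") - 2 * ca %*% t(lig)
    counts <- counts + rowSums(d2 <= cut2)
  }
  out <- data.frame(residue_number = traj$system$residue_number[ica],
                    score = counts / nlig)
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- n_frames(traj)
  attr(out, "n_ligand_heavy") <- nlig
  class(out) <- c("association_profile", "data.frame")
  out
}

#' Probe occupancy z-score grid
#'
#' Bins probe heavy-atom positions from one or more trajectories into a
#' regular voxel grid covering the protein bounding box plus a margin, and
#' converts counts to z-scores over all voxels of that box: the "basal
#' level" against which a density isolevel (e.g. 15 sigma) is defined.
#' Frames are superposed on the protein alpha-carbons of the first frame
#' before binning so densities accumulate on a fixed structure.
#'
#' @param trajs a `labeled_trajectory` or list of them (sharing a topology).
#' @param probe_role role of the probe atoms, default `LIGAND_HEAVY`.
#' @param voxel voxel edge length (Å), default 1.
#' @param margin margin around the protein bounding box (Å), default 5.
#' @param superpose superpose frames on `PROTEIN_CA` before binning.
#' @return An `occupancy_grid`: list with `origin`, `voxel`, `dim`,
#'   `counts` (3D array), `z` (3D array; all-`NA` with `z_defined = FALSE`
#'   when the counts have zero variance), `n_binned`, `n_total`.
#' @export
occupancy_zscore_grid <- function(trajs, probe_role = "LIGAND_HEAVY",
                                  voxel = 1, margin = 5, superpose = TRUE) {
  if (inherits(trajs, "labeled_trajectory")) trajs <- list(trajs)
  stopifnot(voxel > 0, length(trajs) >= 1)
  sys <- trajs[[1]]$system
  ica <- role_indices(sys, "PROTEIN_CA")
  iprobe <- role_indices(sys, probe_role)
  if (length(iprobe) == 0) stop("no probe atoms with role ", probe_role,
                                call. = FALSE)
  ref <- NULL
  pts <- list()
  for (traj in trajs) {
    xyz <- traj$xyz
    if (superpose && length(ica) >= 3) {
      xi <- as.vector(t(cbind(3 * ica - 2, 3 * ica - 1, 3 * ica)))
      if (is.null(ref)) ref <- xyz[1, ]
      xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                            fixed.inds = xi, mobile.inds = xi)
      if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    }
    for (f in seq_len(nrow(xyz))) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      pts[[length(pts) + 1]] <- m[iprobe, , drop = FALSE]
      if (f == 1 && length(pts) == 1) prot_box <- m[ica, , drop = FALSE]
    }
  }
  pts <- do.call(rbind, pts)
  box_ref <- if (length(ica) > 0) prot_box else pts
  lo <- apply(box_ref, 2, min) - margin
  hi <- apply(box_ref, 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / voxel), 1)
  idx <- sweep(pts, 2, lo)
  ijk <- floor(idx / voxel) + 1
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  ijk <- ijk[inside, , drop = FALSE]
  counts <- array(0L, dim = dims)
  if (nrow(ijk) > 0) {
    lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- array(tab, dim = dims)
  }
  mu <- mean(counts)
  sdev <- stats::sd(as.vector(counts))
  z_defined <- is.finite(sdev) && sdev > 0
  z <- if (z_defined) (counts - mu) / sdev else array(NA_real_, dim = dims)
  structure(list(origin = lo, voxel = voxel, dim = dims, counts = counts,
                 z = z, z_defined = z_defined,
                 n_binned = sum(counts), n_total = nrow(pts)),
            class = "occupancy_grid")
}

#' Voxels above a z-score isolevel
#'
#' @param grid an `occupancy_grid`.
#' @param sigma isolevel threshold in standard deviations above the basal
#'   occupancy, default 15 (the isolevel used for probe-density rendering).
#' @return Data frame of voxel indices `i`, `j`, `k`, voxel-center
#'   coordinates `x`, `y`, `z`, and `zscore`.
#' @export
occupancy_hotspots <- function(grid, sigma = 15) {
  if (!grid$z_defined) stop("z-scores undefined: zero count variance",
                            call. = FALSE)
  w <- which(grid$z >= sigma, arr.ind = TRUE)
  if (nrow(w) == 0) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      zscore = numeric()))
  }
  data.frame(
    i = w[, 1], j = w[, 2], k = w[, 3],
    x = grid$origin[1] + (w[, 1] - 0.5) * grid$voxel,
    y = grid$origin[2] + (w[, 2] - 0.5) * grid$voxel,
    z = grid$origin[3] + (w[, 3] - 0.5) * grid$voxel,
    zscore = grid$z[w]
  )
}

#' Write an occupancy grid as OpenDX volumetric text
#'
#' @param grid an `occupancy_grid`.
#' @param path output `.dx` file.
#' @param field `"z"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_opendx <- function(grid, path, field = c("z", "counts")) {
  field <- match.arg(field)
  d <- grid$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.3f %.3f %.3f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.3f 0 0", grid$voxel),
    sprintf("delta 0 %.3f 0", grid$voxel),
    sprintf("delta 0 0 %.3f", grid$voxel),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  # OpenDX expects the last index varying fastest
  arr <- aperm(grid[[field]], c(3, 2, 1))
  v <- as.vector(arr)
  pad <- (-length(v)) %% 3
  if (pad > 0) v <- c(v, rep(NA, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(stats::na.omit(r), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
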