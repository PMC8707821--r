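#' Generate a synthetic membrane-anchored protein system
#'
#' Builds a pseudo-globular Calpha bead protein beneath a planar lipid
#' leaflet, with a 4-atom planar heme proxy at a controlled tilt, so the
#' membrane-validation metrics have exact known ground truth. The membrane
#' normal is the +z axis by construction; the lipid C1 atoms lie exactly in
#' the plane `z = bury_depth` (before jitter) and the protein Calpha
#' centroid sits exactly at the origin, so the burying depth equals
#' `bury_depth`. The porphyrin square starts in the xy-plane (tilt 90
#' degrees) and is rotated about x by `90 - tilt_deg`. Isotropic Gaussian
#' jitter of `noise_sd` is applied independently per frame.
#'
#' @param tilt_deg target heme tilt angle, degrees in \[0, 90\]; default 60.
#' @param bury_depth target burying depth (Å), default 37.
#' @param n_lipids number of lipid C1 atoms, default 50.
#' @param n_residues number of protein residues (one Calpha bead each),
#'   default 100.
#' @param n_frames trajectory length, default 1.
#' @param noise_sd coordinate jitter sd (Å), default 0.
#' @param seed RNG seed.
#' @param frame_interval_ps time per frame (ps), default 50.
#' @param protein_radius radius of the bead protein (Å), default 15.
#' @return A `labeled_trajectory`; attribute `ground_truth` holds the
#'   generating parameters plus the exact Rg of the noiseless protein.
#' @export
make_membrane_system <- function(tilt_deg = 60, bury_depth = 37,
                                 n_lipids = 50, n_residues = 100,
                                 n_frames = 1, noise_sd = 0, seed = 1,
                                 frame_interval_ps = 50,
                                 protein_radius = 15) {
  stopifnot(tilt_deg >= 0, tilt_deg <= 90, bury_depth >= 0, noise_sd >= 0,
            n_lipids >= 1, n_residues >= 3, n_frames >= 1)
  set.seed(seed)
  # protein beads: uniform directions, radii in [0.3, 1] * protein_radius,
  # then recentered so the Calpha centroid is exactly the origin
  u <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- protein_radius * stats::runif(n_residues, 0.3, 1)^(1 / 3)
  ca <- u * rad
  ca <- sweep(ca, 2, colMeans(ca))
  # porphyrin-N square (N-Fe distance ~2.05 Å) tilted about the x-axis
  d <- 2.05
  square <- rbind(c(d, 0, 0), c(0, d, 0), c(-d, 0, 0), c(0, -d, 0))
  phi <- (90 - tilt_deg) * pi / 180
  rotx <- rbind(c(1, 0, 0),
                c(0, cos(phi), -sin(phi)),
                c(0, sin(phi), cos(phi)))
  hem <- square %*% t(rotx)
  # lipid C1 plane at z = bury_depth
  lip <- cbind(stats::runif(n_lipids, -30, 30),
               stats::runif(n_lipids, -30, 30),
               rep(bury_depth, n_lipids))
  ideal <- rbind(ca, hem, lip)
  atom <- data.frame(
    elety = c(rep("CA", n_residues), c("NA", "NB", "NC", "ND"),
              rep("C1", n_lipids)),
    resid = c(rep("ALA", n_residues), rep("HEM", 4), rep("POP", n_lipids)),
    elesy = c(rep("C", n_residues), rep("N", 4), rep("C", n_lipids)),
    stringsAsFactors = FALSE
  )
  resno <- c(seq_len(n_residues), rep(n_residues + 1, 4),
             n_residues + 1 + seq_len(n_lipids))
  sys <- data.frame(
    atom_id = seq_len(nrow(atom)),
    atom_name = atom$elety,
    residue_number = resno,
    residue_name = atom$resid,
    chain = "A",
    element = atom$elesy,
    role = assign_roles(atom),
    stringsAsFactors = FALSE
  )
  class(sys) <- c("labeled_system", "data.frame")
  natom <- nrow(sys)
  xyz <- matrix(NA_real_, nrow = n_frames, ncol = 3 * natom)
  flat <- as.numeric(t(ideal))
  for (f in seq_len(n_frames)) {
    xyz[f, ] <- flat + if (noise_sd > 0)
      stats::rnorm(3 * natom, sd = noise_sd) else 0
  }
  traj <- labeled_trajectory(sys, xyz, frame_interval_ps)
  attr(traj, "ground_truth") <- list(
    tilt_deg = tilt_deg, bury_depth = bury_depth,
    rg = radius_of_gyration(ca),
    n_lipids = n_lipids, n_residues = n_residues,
    noise_sd = noise_sd, seed = seed
  )
  traj
}

#' Append a synthetic ligand random walk with a known egress
#'
#' Adds a rigid cluster of ligand heavy atoms to a protein trajectory. The
#' ligand wanders next to protein atoms (minimum distance below the
#' dissociation cutoff) until `egress_frame`, then leaves along the
#' direction of `exit_anchor` with strictly growing clearance, so the
#' dissociation frame and exit direction are known exactly. An optional
#' single-frame excursion above the cutoff before the true egress tests
#' persistence filtering.
#'
#' @param traj a `labeled_trajectory` with `PROTEIN_CA` atoms (e.g. from
#'   [make_membrane_system()]).
#' @param exit_anchor 3D point the ligand exits toward (Å).
#' @param egress_frame first frame of permanent dissociation; must leave at
#'   least `persistence_frames` frames to the end of the trajectory.
#' @param persistence_frames frames the ligand must stay dissociated,
#'   default 10.
#' @param threshold dissociation cutoff (Å), default 5.
#' @param n_lig_atoms ligand heavy-atom count, default 5.
#' @param seed RNG seed.
#' @param excursion_frame optional frame (< egress_frame) of a 1-frame
#'   excursion above the cutoff.
#' @return A `labeled_trajectory` including the ligand; attribute
#'   `ground_truth` records `egress_frame` and `exit_anchor`.
#' @export
make_ligand_walk <- function(traj, exit_anchor, egress_frame,
                             persistence_frames = 10, threshold = 5,
                             n_lig_atoms = 5, seed = 1,
                             excursion_frame = NULL) {
  nf <- n_frames(traj)
  stopifnot(egress_frame >= 1, egress_frame <= nf)
  if (egress_frame + persistence_frames - 1 > nf) {
    stop("egress_frame leaves fewer than persistence_frames frames",
         call. = FALSE)
  }
  if (!is.null(excursion_frame) && excursion_frame >= egress_frame) {
    stop("excursion_frame must precede egress_frame", call. = FALSE)
  }
  set.seed(seed)
  sys <- traj$system
  ica <- role_indices(sys, "PROTEIN_CA")
  ca1 <- frame_coords(traj, 1, ica)
  center <- colMeans(ca1)
  rmax <- sqrt(max(rowSums(sweep(ca1, 2, center)^2)))
  u <- exit_anchor - center
  u <- u / sqrt(sum(u^2))
  # rigid ligand shape around its center of mass (centered exactly)
  shape <- matrix(stats::rnorm(3 * n_lig_atoms, sd = 0.8), ncol = 3)
  shape <- sweep(shape, 2, colMeans(shape))
  coms <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) {
    if (f >= egress_frame) {
      dist_out <- rmax + threshold + 2 + 3 * (f - egress_frame)
      coms[f, ] <- center + u * dist_out
    } else if (!is.null(excursion_frame) && f == excursion_frame) {
      coms[f, ] <- center + u * (rmax + threshold + 2)
    } else {
      # bound to a random surface bead: COM within 1 Å of some Calpha
      bead <- ca1[sample(nrow(ca1), 1), ]
      coms[f, ] <- bead + stats::rnorm(3, sd = 0.3)
    }
  }
  lig_sys <- data.frame(
    atom_id = nrow(sys) + seq_len(n_lig_atoms),
    atom_name = paste0("C", seq_len(n_lig_atoms)),
    residue_number = max(sys$residue_number) + 1,
    residue_name = "LIG",
    chain = "L",
    element = "C",
    role = "LIGAND_HEAVY",
    stringsAsFactors = FALSE
  )
  new_sys <- rbind(as.data.frame(sys), lig_sys)
  class(new_sys) <- c("labeled_system", "data.frame")
  new_xyz <- matrix(NA_real_, nf, 3 * nrow(new_sys))
  for (f in seq_len(nf)) {
    lig <- sweep(shape, 2, coms[f, ], "+")
    new_xyz[f, ] <- c(traj$xyz[f, ], as.numeric(t(lig)))
  }
  out <- labeled_trajectory(new_sys, new_xyz, traj$frame_interval_ps)
  attr(out, "ground_truth") <- c(
    attr(traj, "ground_truth"),
    list(egress_frame = as.integer(egress_frame),
         exit_anchor = exit_anchor,
         excursion_frame = excursion_frame)
  )
  out
}

#' Generate a synthetic alignment with known conservation
#'
#' Builds a reference sequence plus `n_seqs - 1` identical variant
#' sequences whose residues at the site positions follow `identity_plan`:
#' `"identical"` keeps the reference residue, `"group"` substitutes a
#' different residue from the same physicochemical group, `"different"`
#' substitutes a residue from another group. The expected pairwise
#' conservation and identity matrices follow directly from the plan.
#'
#' @param n_seqs number of sequences (>= 2), default 2.
#' @param site_positions 1-based positions of the site on the reference.
#' @param identity_plan character vector (one of `"identical"`, `"group"`,
#'   `"different"` per site position).
#' @param seq_length reference length; default `max(site_positions) + 10`.
#' @param seed RNG seed.
#' @param scheme group scheme, see [default_group_scheme()].
#' @return List with `alignment` (character matrix, rows named `ref`,
#'   `var1`, ...), `site` (a `site_definition` anchored on `ref`),
#'   `expected_c` and `expected_identity` matrices.
#' @export
make_alignment <- function(n_seqs = 2, site_positions,
                           identity_plan,
                           seq_length = max(site_positions) + 10,
                           seed = 1, scheme = default_group_scheme()) {
  stopifnot(n_seqs >= 2,
            length(identity_plan) == length(site_positions),
            all(identity_plan %in% c("identical", "group", "different")),
            max(site_positions) <= seq_length)
  set.seed(seed)
  aa <- unlist(scheme, use.names = FALSE)
  group_of <- function(x) names(which(vapply(scheme, function(g) x %in% g,
                                             logical(1))))
  ref <- sample(aa, seq_length, replace = TRUE)
  var <- ref
  for (k in seq_along(site_positions)) {
    p <- site_positions[k]
    g <- group_of(ref[p])
    var[p] <- switch(identity_plan[k],
      identical = ref[p],
      group = sample(setdiff(scheme[[g]], ref[p]), 1),
      different = sample(unlist(scheme[setdiff(names(scheme), g)],
                                use.names = FALSE), 1)
    )
  }
  ali <- rbind(ref, matrix(rep(var, n_seqs - 1), nrow = n_seqs - 1,
                           byrow = TRUE))
  rownames(ali) <- c("ref", paste0("var", seq_len(n_seqs - 1)))
  plan_score <- mean(c(identical = 1, group = 0.5,
                       different = 0)[identity_plan])
  # identity over the site only (non-site columns are shared by design)
  site_ident <- 100 * mean(identity_plan == "identical")
  ec <- matrix(1, n_seqs, n_seqs)
  ei <- matrix(100, n_seqs, n_seqs)
  ec[1, -1] <- ec[-1, 1] <- plan_score
  ei[1, -1] <- ei[-1, 1] <- site_ident
  labels <- rownames(ali)
  dimnames(ec) <- dimnames(ei) <- list(labels, labels)
  list(
    alignment = ali,
    site = site_definition("ref", site_positions, ref[site_positions]),
    expected_c = ec,
    expected_identity = ei
  )
}

#' Write a hills schedule to a readable hills file
#'
#' @param schedule data frame (or `hills_table`) with columns `time`,
#'   `center`, `width`, `height`; may be empty.
#' @param path output file.
#' @return `path`, invisibly; reading it back with [read_hills()]
#'   reproduces the schedule.
#' @export
make_hills <- function(schedule, path) {
  stopifnot(all(c("time", "center", "width", "height") %in% names(schedule)))
  write_hills(schedule, path)
}

#' Build a clearance grid with known maximin bottleneck
#'
#' Starts from a fully blocked grid (clearance 0 everywhere) and carves one
#' or more corridors, each a 6-connected voxel path from the start voxel to
#' the grid boundary with a prescribed clearance profile. The known
#' bottleneck is the best corridor's worst clearance: `max` over corridors
#' of `min` clearance along that corridor.
#'
#' @param dims grid dimensions (nx, ny, nz).
#' @param corridors list of corridors, each `list(path = <n x 3 voxel
#'   matrix>, clearance = <scalar or per-voxel vector>)`. Every path must
#'   begin at `start`, step between face-adjacent voxels, and end on the
#'   grid boundary; anything else is an error.
#' @param start start voxel (i, j, k).
#' @param spacing voxel edge (Å), default 1.
#' @return List with `grid` (a `clearance_grid`), `start` and
#'   `true_bottleneck`.
#' @export
make_tunnel_grid <- function(dims, corridors, start, spacing = 1) {
  stopifnot(length(dims) == 3, all(dims >= 1), length(corridors) >= 1)
  cl <- array(0, dim = dims)
  mins <- numeric(length(corridors))
  for (ci in seq_along(corridors)) {
    cor <- corridors[[ci]]
    path <- matrix(as.integer(cor$path), ncol = 3)
    clear <- rep(cor$clearance, length.out = nrow(path))
    if (any(clear <= 0)) stop("corridor clearances must be > 0", call. = FALSE)
    if (!all(path[1, ] == start)) {
      stop("corridor ", ci, " does not begin at the start voxel",
           call. = FALSE)
    }
    if (nrow(path) > 1) {
      steps <- abs(diff(path))
      if (any(rowSums(steps) != 1)) {
        stop("corridor ", ci, " is disconnected (non-adjacent voxels)",
             call. = FALSE)
      }
    }
    if (any(path < 1) || any(sweep(path, 2, dims, ">") == 1)) {
      stop("corridor ", ci, " leaves the grid", call. = FALSE)
    }
    last <- path[nrow(path), ]
    if (!.is_boundary(last, dims)) {
      stop("corridor ", ci, " does not reach the grid boundary",
           call. = FALSE)
    }
    for (r in seq_len(nrow(path))) {
      v <- path[r, ]
      cl[v[1], v[2], v[3]] <- max(cl[v[1], v[2], v[3]], clear[r])
    }
    mins[ci] <- min(clear)
  }
  list(grid = clearance_grid(cl, spacing), start = as.integer(start),
       true_bottleneck = max(mins))
}

#' Write a ground-truth sidecar next to a generated fixture
#'
#' @param truth list of ground-truth values (e.g. the `ground_truth`
#'   attribute of a generated trajectory).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
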