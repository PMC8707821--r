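#' Parse CAVER-style per-frame bottleneck profiles
#'
#' Reads a CSV with one row per (frame, tunnel) holding the bottleneck
#' radius of that tunnel in that frame. Frames where a tunnel was not found
#' are simply absent from that tunnel's series. Duplicated (frame, tunnel)
#' rows are an error, never silently averaged.
#'
#' @param path CSV file. Recognized column names (case-insensitive):
#'   frame; tunnel / cluster / tunnel_id; bottleneck_radius / radius / r_b.
#' @return Named list of `bottleneck_series`, one per tunnel id.
#' @export
parse_caver_profiles <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  fcol <- which(nm == "frame")
  tcol <- which(nm %in% c("tunnel", "cluster", "tunnel_id"))
  rcol <- which(nm %in% c("bottleneck_radius", "radius", "r_b"))
  if (length(fcol) != 1 || length(tcol) != 1 || length(rcol) != 1) {
    stop("CAVER profile '", path, "' must have columns frame, ",
         "tunnel/cluster and bottleneck_radius/radius/r_b", call. = FALSE)
  }
  key <- paste(tab[[fcol]], tab[[tcol]], sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (frame, tunnel) rows in '", path, "'", call. = FALSE)
  }
  ids <- sort(unique(as.character(tab[[tcol]])))
  out <- lapply(ids, function(id) {
    sel <- as.character(tab[[tcol]]) == id
    bottleneck_series(id, r = tab[[rcol]][sel], frames = tab[[fcol]][sel])
  })
  names(out) <- ids
  out
}

#' Construct a per-frame bottleneck-radius series for one tunnel
#'
#' @param tunnel_id tunnel label, e.g. `"2b"`, `"2c"`, `"2f"`.
#' @param r bottleneck radii (Å), strictly positive, one per frame in which
#'   the tunnel was found.
#' @param frames optional frame indices.
#' @return A `bottleneck_series` list with `tunnel_id`, `r`, `frames`,
#'   `mean`, `sd`, `n`.
#' @export
bottleneck_series <- function(tunnel_id, r, frames = seq_along(r)) {
  if (any(r <= 0)) stop("bottleneck radii must be > 0 where present",
                        call. = FALSE)
  structure(list(tunnel_id = tunnel_id, r = as.numeric(r),
                 frames = frames,
                 mean = if (length(r)) mean(r) else NA_real_,
                 sd = if (length(r) > 1) stats::sd(r) else NA_real_,
                 n = length(r)),
            class = "bottleneck_series")
}

#' Compare bottleneck radii between two conditions
#'
#' Welch two-sided t-test from summary statistics on the per-frame
#' bottleneck radii of one tunnel in two conditions (typically: allosteric
#' ligand bound vs membrane equilibration). Direction is `"+"` when
#' condition `a` has the significantly larger mean, `"-"` when smaller,
#' `"="` when not significant, and `"n/a"` when the tunnel is absent
#' (empty series or `NULL`) in either condition.
#'
#' @param a,b `bottleneck_series` for the two conditions (`NULL` = tunnel
#'   not present).
#' @param alpha significance level, default 0.1.
#' @return A `tunnel_outcome`: list with `tunnel_id`, `direction`, `p`.
#' @export
compare_bottlenecks <- function(a, b, alpha = 0.1) {
  id <- if (!is.null(a)) a$tunnel_id else if (!is.null(b)) b$tunnel_id else NA
  absent <- function(x) is.null(x) || x$n == 0
  if (absent(a) || absent(b)) {
    return(structure(list(tunnel_id = id, direction = "n/a", p = NA_real_),
                     class = "tunnel_outcome"))
  }
  if (a$n < 2 || b$n < 2) {
    stop("need n >= 2 frames per condition for a t-test", call. = FALSE)
  }
  wt <- welch_ttest_from_stats(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
  dir <- if (wt$p < alpha) {
    if (a$mean > b$mean) "+" else "-"
  } else "="
  structure(list(tunnel_id = id, direction = dir, p = wt$p),
            class = "tunnel_outcome")
}

#' Construct a clearance grid
#'
#' Regular 3D grid whose voxel values are clearances: the distance from the
#' voxel center to the nearest protein atom minus the probe radius. A voxel
#' is passable when its clearance is positive.
#'
#' @param clearance 3D numeric array of clearances (Å).
#' @param spacing voxel edge length (Å), default 1.
#' @return A `clearance_grid` list.
#' @export
clearance_grid <- function(clearance, spacing = 1) {
  stopifnot(is.array(clearance), length(dim(clearance)) == 3,
            spacing > 0, all(is.finite(clearance)))
  structure(list(clearance = clearance, spacing = spacing,
                 dim = dim(clearance)),
            class = "clearance_grid")
}

#' Build a clearance grid from protein coordinates
#'
#' @param coords N x 3 protein atom coordinates (Å).
#' @param spacing voxel edge (Å), default 1.
#' @param margin box margin (Å), default 5.
#' @param probe_radius subtracted from the nearest-atom distance, default 0.
#' @return A `clearance_grid` with an `origin` element.
#' @export
clearance_grid_from_coords <- function(coords, spacing = 1, margin = 5,
                                       probe_radius = 0) {
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / spacing), 1)
  centers <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 0.5) * spacing)
  g <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
  d2 <- outer(rowSums(g^2), rowSums(coords^2), "+") - 2 * g %*% t(coords)
  d2[d2 < 0] <- 0
  cl <- array(sqrt(apply(d2, 1, min)) - probe_radius, dim = dims)
  out <- clearance_grid(cl, spacing)
  out$origin <- lo
  out
}

.grid_neighbors <- function(v, dims) {
  # 6-connected (face-adjacent) neighbors
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- sweep(steps, 2, v, "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
  nb[ok, , drop = FALSE]
}

.is_boundary <- function(v, dims) {
  any(v == 1) || any(v == dims)
}

#' Widest-path (maximin-clearance) bottleneck search on a grid
#'
#' Finds, by a priority search over 6-connected voxels, the path from the
#' start voxel to any goal voxel that maximizes the minimum clearance along
#' the path; that minimum is the tunnel's bottleneck radius. This is a
#' deliberately simplified geometric bottleneck finder for desk-scale
#' synthetic systems, not a Voronoi-based tunnel computation.
#'
#' @param grid a `clearance_grid`.
#' @param start integer vector (i, j, k), 1-based; must have positive
#'   clearance.
#' @param goals matrix of goal voxels (rows of i, j, k); default all
#'   boundary voxels of the grid.
#' @return List with `found` (logical), `bottleneck` (Å; `NA` when no
#'   positive-clearance path exists) and `path` (matrix of voxels from
#'   start to the reached goal; `NULL` when not found).
#' @export
grid_bottleneck <- function(grid, start, goals = NULL) {
  cl <- grid$clearance
  dims <- dim(cl)
  start <- as.integer(start)
  stopifnot(length(start) == 3, all(start >= 1), all(start <= dims))
  if (cl[start[1], start[2], start[3]] <= 0) {
    stop("start voxel has non-positive clearance", call. = FALSE)
  }
  lin <- function(v) v[1] + dims[1] * (v[2] - 1) + dims[1] * dims[2] * (v[3] - 1)
  is_goal <- rep(FALSE, prod(dims))
  if (is.null(goals)) {
    idx <- which(array(TRUE, dims), arr.ind = TRUE)
    bnd <- idx[, 1] == 1 | idx[, 1] == dims[1] |
           idx[, 2] == 1 | idx[, 2] == dims[2] |
           idx[, 3] == 1 | idx[, 3] == dims[3]
    is_goal[apply(idx[bnd, , drop = FALSE], 1, lin)] <- TRUE
  } else {
    goals <- matrix(as.integer(goals), ncol = 3)
    is_goal[apply(goals, 1, lin)] <- TRUE
  }
  n <- prod(dims)
  best <- rep(-Inf, n)     # best bottleneck achievable reaching each voxel
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  s <- lin(start)
  best[s] <- cl[start[1], start[2], start[3]]
  unlin <- function(l) {
    k <- (l - 1) %/% (dims[1] * dims[2])
    rem <- (l - 1) %% (dims[1] * dims[2])
    c(rem %% dims[1] + 1, rem %/% dims[1] + 1, k + 1)
  }
  repeat {
    cand <- which(!done & best > 0)
    if (length(cand) == 0) break
    u <- cand[which.max(best[cand])]
    done[u] <- TRUE
    uv <- unlin(u)
    if (is_goal[u]) {
      # reconstruct path
      path <- list()
      cur <- u
      while (!is.na(cur)) {
        path[[length(path) + 1]] <- unlin(cur)
        cur <- prev[cur]
      }
      path <- do.call(rbind, rev(path))
      return(list(found = TRUE, bottleneck = best[u], path = path))
    }
    nbs <- .grid_neighbors(uv, dims)
    for (r in seq_len(nrow(nbs))) {
      nv <- nbs[r, ]
      nl <- lin(nv)
      if (done[nl]) next
      ncl <- cl[nv[1], nv[2], nv[3]]
      if (ncl <= 0) next
      cand_b <- min(best[u], ncl)
      if (cand_b > best[nl]) {
        best[nl] <- cand_b
        prev[nl] <- u
      }
    }
  }
  list(found = FALSE, bottleneck = NA_real_, path = NULL)
}

#' First frame where the ligand crosses the protein surface
#'
#' The crossing is the first frame at which the ligand center-of-mass
#' distance to the nearest protein atom exceeds `threshold`, consistent
#' with the dissociation criterion used for the metadynamics readouts.
#'
#' @param traj a `labeled_trajectory` with ligand and protein atoms.
#' @param threshold distance cutoff (Å), default 5.
#' @param protein_roles roles counted as protein, default
#'   `c("PROTEIN_CA", "PORPHYRIN_N")`.
#' @return 1-based frame index, or `NA_integer_` when no crossing occurs.
#' @export
surface_crossing_frame <- function(traj, threshold = 5,
                                   protein_roles = c("PROTEIN_CA",
                                                     "PORPHYRIN_N")) {
  iprot <- which(traj$system$role %in% protein_roles)
  ilig <- role_indices(traj$system, "LIGAND_HEAVY")
  if (length(iprot) == 0 || length(ilig) == 0) {
    stop("need protein and ligand atoms", call. = FALSE)
  }
  for (f in seq_len(n_frames(traj))) {
    com <- colMeans(frame_coords(traj, f, ilig))
    prot <- frame_coords(traj, f, iprot)
    dmin <- sqrt(min(rowSums(sweep(prot, 2, com)^2)))
    if (dmin > threshold) return(f)
  }
  NA_integer_
}

#' Minimum ligand-to-protein distance per frame
#'
#' @param traj a `labeled_trajectory`.
#' @param protein_roles roles counted as protein.
#' @param use_com measure from the ligand center of mass (default) rather
#'   than the closest ligand atom.
#' @return Numeric vector, one distance (Å) per frame.
#' @export
ligand_min_distance <- function(traj,
                                protein_roles = c("PROTEIN_CA",
                                                  "PORPHYRIN_N"),
                                use_com = TRUE) {
  iprot <- which(traj$system$role %in% protein_roles)
  ilig <- role_indices(traj$system, "LIGAND_HEAVY")
  if (length(iprot) == 0 || length(ilig) == 0) {
    stop("need protein and ligand atoms", call. = FALSE)
  }
  vapply(seq_len(n_frames(traj)), function(f) {
    prot <- frame_coords(traj, f, iprot)
    lig <- frame_coords(traj, f, ilig)
    if (use_com) lig <- matrix(colMeans(lig), ncol = 3)
    d2 <- outer(rowSums(lig^2), rowSums(prot^2), "+") - 2 * lig %*% t(prot)
    sqrt(max(min(d2), 0))
  }, numeric(1))
}

#' Classify the egress pathway of a dissociating ligand
#'
#' Assigns the tunnel whose anchor point is nearest (Euclidean) to the
#' ligand center of mass at the first surface-crossing frame. Ties are
#' broken lexicographically on the tunnel id, deterministically.
#'
#' @param com_trace frames x 3 matrix of ligand center-of-mass positions.
#' @param anchors named list (or 3-column matrix with rownames) of tunnel
#'   anchor points, e.g. `list("2b" = c(...), "2f" = c(...))`.
#' @param crossing_frame the surface-crossing frame (see
#'   [surface_crossing_frame()]).
#' @return Tunnel id (character).
#' @export
classify_egress_pathway <- function(com_trace, anchors, crossing_frame) {
  if (is.na(crossing_frame)) {
    stop("no surface crossing: ligand never left the protein", call. = FALSE)
  }
  if (is.list(anchors)) {
    anchors <- do.call(rbind, anchors)
  }
  stopifnot(!is.null(rownames(anchors)), nrow(anchors) >= 1)
  com <- as.numeric(com_trace[crossing_frame, ])
  d <- sqrt(rowSums(sweep(anchors, 2, com)^2))
  ids <- rownames(anchors)
  ord <- order(d, ids)     # lexicographic tie-break on tunnel id
  ids[ord[1]]
}
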