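# Independent oracles used across test files. These deliberately avoid the
# implementation paths they check.

# Maximin bottleneck by exhaustive DFS over all simple paths from start to
# any boundary voxel. Only feasible on small/sparse grids.
brute_maximin_paths <- function(clearance, start) {
  dims <- dim(clearance)
  is_boundary <- function(v) any(v == 1) || any(v == dims)
  best <- -Inf
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  visited <- array(FALSE, dims)
  dfs <- function(v, cur_min) {
    if (cur_min <= best) return(invisible())  # cannot beat the incumbent
    if (is_boundary(v)) best <<- max(best, cur_min)
    for (r in seq_len(nrow(nb))) {
      w <- v + nb[r, ]
      if (any(w < 1) || any(w > dims)) next
      if (visited[w[1], w[2], w[3]]) next
      cw <- clearance[w[1], w[2], w[3]]
      if (cw <= 0) next
      visited[w[1], w[2], w[3]] <<- TRUE
      dfs(w, min(cur_min, cw))
      visited[w[1], w[2], w[3]] <<- FALSE
    }
  }
  c0 <- clearance[start[1], start[2], start[3]]
  if (c0 <= 0) return(NA_real_)
  visited[start[1], start[2], start[3]] <- TRUE
  dfs(start, c0)
  if (is.finite(best)) best else NA_real_
}

# Maximin bottleneck by threshold sweep + flood fill: the bottleneck is the
# largest clearance level at which the start still reaches the boundary
# through voxels at or above that level. Exhaustive over all candidate
# levels, polynomial, and independent of any priority search.
flood_maximin <- function(clearance, start) {
  dims <- dim(clearance)
  c0 <- clearance[start[1], start[2], start[3]]
  if (c0 <= 0) return(NA_real_)
  levels <- sort(unique(clearance[clearance > 0 & clearance <= c0]),
                 decreasing = TRUE)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (lev in levels) {
    open <- clearance >= lev
    if (!open[start[1], start[2], start[3]]) next
    reach <- array(FALSE, dims)
    reach[start[1], start[2], start[3]] <- TRUE
    queue <- list(start)
    hit <- any(start == 1) || any(start == dims)
    while (length(queue) > 0 && !hit) {
      v <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(nb))) {
        w <- v + nb[r, ]
        if (any(w < 1) || any(w > dims)) next
        if (!open[w[1], w[2], w[3]] || reach[w[1], w[2], w[3]]) next
        reach[w[1], w[2], w[3]] <- TRUE
        if (any(w == 1) || any(w == dims)) { hit <- TRUE; break }
        queue[[length(queue) + 1]] <- w
      }
    }
    if (hit) return(lev)
  }
  NA_real_
}

# Direct double-loop recount of per-residue ligand contacts.
brute_association <- function(traj, cutoff = 5) {
  ica <- role_indices(traj$system, "PROTEIN_CA")
  ilig <- role_indices(traj$system, "LIGAND_HEAVY")
  counts <- numeric(length(ica))
  for (f in seq_len(n_frames(traj))) {
    ca <- frame_coords(traj, f, ica)
    lig <- frame_coords(traj, f, ilig)
    for (i in seq_along(ica)) {
      for (j in seq_along(ilig)) {
        if (sqrt(sum((ca[i, ] - lig[j, ])^2)) <= cutoff) {
          counts[i] <- counts[i] + 1
        }
      }
    }
  }
  counts / length(ilig)
}

# Textbook Welch formula written independently of the package version.
oracle_welch <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Minimal membrane system reused by several files.
tiny_system <- function(...) make_membrane_system(n_residues = 20,
                                                  n_lipids = 10, ...)
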