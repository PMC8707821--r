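#' Table of deposited metadynamics Gaussians
#'
#' One row per hill: deposition time (ps), collective-variable center (Å),
#' Gaussian width sigma (Å) and height (kcal/mol). The collective variable
#' in the egress protocol is the distance between the ligand centroid and
#' the heme iron. The production defaults are a height of 0.03 kcal/mol and
#' a width of 0.05 Å. Rows are kept sorted by time.
#'
#' @param time deposition times (ps).
#' @param center CV centers (Å).
#' @param width Gaussian widths sigma (Å), strictly positive.
#' @param height Gaussian heights (kcal/mol), strictly positive.
#' @return A `hills_table` data frame.
#' @export
hills_table <- function(time = numeric(), center = numeric(),
                        width = numeric(), height = numeric()) {
  n <- length(time)
  if (n > 0) {
    center <- rep(center, length.out = n)
    width <- rep(width, length.out = n)
    height <- rep(height, length.out = n)
  }
  if (any(width <= 0)) stop("hill widths must be > 0", call. = FALSE)
  if (any(height <= 0)) stop("hill heights must be > 0", call. = FALSE)
  h <- data.frame(time = as.numeric(time), center = as.numeric(center),
                  width = as.numeric(width), height = as.numeric(height))
  h <- h[order(h$time), , drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("hills_table", "data.frame")
  h
}

#' Reconstruct the deposited bias potential
#'
#' Sums all Gaussians deposited up to time `t`:
#' `V(s, t) = sum_{t_i <= t} h_i * exp(-(s - s_i)^2 / (2 sigma_i^2))`.
#' With a single default hill evaluated at its own center this is the hill
#' height, 0.03 kcal/mol. `V(s, t)` is non-negative and non-decreasing in
#' `t` for every fixed `s`, since hills only accumulate.
#'
#' @param hills a `hills_table`.
#' @param s CV value(s) (Å); vectorized.
#' @param t evaluation time (ps); hills deposited after `t` are excluded.
#'   Default `Inf` sums the full table.
#' @param width_is_fwhm interpret the width column as full width at half
#'   maximum instead of sigma (`sigma = FWHM / (2 sqrt(2 ln 2))`).
#' @return Bias potential in kcal/mol, same length as `s`.
#' @export
bias_potential <- function(hills, s, t = Inf, width_is_fwhm = FALSE) {
  act <- hills[hills$time <= t, , drop = FALSE]
  if (nrow(act) == 0) return(rep(0, length(s)))
  sig <- act$width
  if (width_is_fwhm) sig <- sig / (2 * sqrt(2 * log(2)))
  vapply(s, function(si) {
    sum(act$height * exp(-(si - act$center)^2 / (2 * sig^2)))
  }, numeric(1))
}

#' Detect the ligand dissociation frame from a minimum-distance series
#'
#' The ligand counts as dissociated at the first frame opening a run of at
#' least `persistence` consecutive frames whose minimum ligand-to-protein
#' heavy-atom distance all exceed `threshold`. Short excursions that return
#' below the threshold are ignored. The persistence requirement is the
#' reproducible stand-in for a visual "complete dissociation" call.
#'
#' Absence of egress is a value, not an error: some replicas never
#' dissociate within the simulated time.
#'
#' @param min_distance per-frame minimum ligand-protein distance (Å).
#' @param threshold dissociation cutoff (Å), default 5.
#' @param persistence required run length in frames, default 10.
#' @return The 1-based frame index of dissociation, or `NA_integer_` when no
#'   qualifying run exists.
#' @export
detect_egress_time <- function(min_distance, threshold = 5, persistence = 10) {
  stopifnot(length(min_distance) > 0, persistence >= 1)
  above <- min_distance > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= persistence)
  if (length(ok) == 0) return(NA_integer_)
  as.integer(starts[ok[1]])
}

#' Maximal deposited potential at the moment of dissociation
#'
#' Scans the bias `V(s, t_egress)` on a regular CV grid from 0 to the wall
#' and returns its maximum. The 45 Å wall is the upper CV bound used during
#' deposition; the grid spacing defaults to half the narrowest hill width so
#' no Gaussian can slip between grid points.
#'
#' @param hills a `hills_table`.
#' @param t_egress evaluation time (ps), typically the dissociation time.
#'   For replicas without egress pass the final simulation time (the result
#'   should then be flagged by the caller).
#' @param wall CV upper bound (Å), default 45.
#' @param spacing grid spacing (Å); default `min(width) / 2`.
#' @param cv_trace optional per-frame CV values; when supplied together with
#'   `times`, the maximum of the bias experienced along the trajectory up to
#'   `t_egress` is returned instead of the grid maximum.
#' @param times frame times (ps) matching `cv_trace`.
#' @return Maximal potential in kcal/mol.
#' @export
p_max <- function(hills, t_egress = Inf, wall = 45, spacing = NULL,
                  cv_trace = NULL, times = NULL) {
  if (!is.null(cv_trace)) {
    stopifnot(!is.null(times), length(times) == length(cv_trace))
    keep <- times <= t_egress
    if (!any(keep)) return(0)
    v <- mapply(function(s, tt) bias_potential(hills, s, tt),
                cv_trace[keep], times[keep])
    return(max(v))
  }
  if (nrow(hills) == 0) return(0)
  if (is.null(spacing)) spacing <- min(hills$width) / 2
  grid <- seq(0, wall, by = spacing)
  max(bias_potential(hills, grid, t_egress))
}

#' Compare egress readouts between allosteric and control groups
#'
#' Two-sided Welch t-test on a per-replica metric (dissociation time or
#' maximal potential). The outcome label names the group with the lower
#' mean: `"H1"` when the allosteric-ligand group dissociates faster /
#' cheaper, `"WAT"` when the control (no allosteric ligand) does.
#'
#' @param allosteric metric values for replicas with an allosteric ligand
#'   bound to the H1 site.
#' @param control metric values for replicas without one.
#' @param alpha significance level, default 0.1.
#' @return List with `label` ("H1" or "WAT"), `p`, `t`, `df`,
#'   `significant` (p < alpha), and the two group means.
#' @export
egress_group_compare <- function(allosteric, control, alpha = 0.1) {
  if (length(allosteric) < 2 || length(control) < 2) {
    stop("need at least 2 replicas per group", call. = FALSE)
  }
  wt <- welch_ttest_from_stats(
    mean(allosteric), stats::sd(allosteric), length(allosteric),
    mean(control), stats::sd(control), length(control)
  )
  list(
    label = if (mean(allosteric) <= mean(control)) "H1" else "WAT",
    p = wt$p, t = wt$t, df = wt$df,
    significant = wt$p < alpha,
    mean_allosteric = mean(allosteric), mean_control = mean(control)
  )
}

#' Assemble a per-replica egress readout
#'
#' Convenience wrapper combining dissociation detection, maximal potential
#' and pathway classification into the readout reported per metadynamics
#' replica.
#'
#' @param min_distance per-frame minimum ligand-protein distance (Å).
#' @param hills a `hills_table`.
#' @param frame_interval_ps time per frame (ps).
#' @param threshold,persistence see [detect_egress_time()].
#' @param wall CV upper bound (Å).
#' @param pathway optional tunnel label from [classify_egress_pathway()].
#' @return List with `egressed`, `frame`, `delta_t_ns`, `p_max_kcal_mol`,
#'   `pathway`.
#' @export
egress_readout <- function(min_distance, hills, frame_interval_ps = 50,
                           threshold = 5, persistence = 10, wall = 45,
                           pathway = NA_character_) {
  fr <- detect_egress_time(min_distance, threshold, persistence)
  n <- length(min_distance)
  t_end <- (n - 1) * frame_interval_ps
  if (is.na(fr)) {
    t_eval <- t_end
    dt <- NA_real_
  } else {
    t_eval <- (fr - 1) * frame_interval_ps
    dt <- t_eval / 1000
  }
  list(egressed = !is.na(fr), frame = fr, delta_t_ns = dt,
       p_max_kcal_mol = p_max(hills, t_eval, wall = wall),
       pathway = pathway)
}
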