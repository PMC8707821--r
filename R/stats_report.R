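#' Welch t-test from summary statistics
#'
#' Two-sided two-sample t-test with unequal variances computed from group
#' means, sample standard deviations (ddof = 1) and sizes, using the
#' Welch-Satterthwaite degrees of freedom. This is the summary-statistics
#' form used for all bottleneck and egress comparisons, at a significance
#' level of p = 0.1 throughout the pipeline.
#'
#' When both standard deviations are zero the statistic is degenerate: with
#' equal means the conventional p = 1 is returned; with different means the
#' call errors.
#'
#' @param mean1,sd1,n1 first group: mean, sample sd, size (n >= 2).
#' @param mean2,sd2,n2 second group.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
welch_ttest_from_stats <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}

#' Default simulation plan
#'
#' The study design: per enzyme, ten 60 ns cosolvent runs, one 500 ns
#' ligand-association run, one 300 ns membrane equilibration, three 1005 ns
#' sampling replicas with an allosteric ligand, and ten 50 ns metadynamics
#' replicas each with and without the allosteric ligand.
#'
#' @return A `simulation_plan` data frame with columns `type`, `membrane`,
#'   `duration_ns`, `replicas`, `lig_ortho`, `lig_allo`.
#' @export
simulation_plan <- function() {
  p <- data.frame(
    type = c("cosolvent", "association", "equilibration", "sampling",
             "metadynamics_control", "metadynamics_allosteric"),
    membrane = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    duration_ns = c(60, 500, 300, 1005, 50, 50),
    replicas = c(10, 1, 1, 3, 10, 10),
    lig_ortho = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    lig_allo = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  class(p) <- c("simulation_plan", "data.frame")
  p
}

#' Total simulated time of a plan
#'
#' @param plan a `simulation_plan` (default the study design).
#' @param n_enzymes number of enzymes, default 9.
#' @return List with `per_enzyme_ns`, `total_ns`, and a `by_type` data
#'   frame of per-type subtotals across all enzymes.
#' @export
plan_total_time <- function(plan = simulation_plan(), n_enzymes = 9) {
  stopifnot(all(plan$duration_ns > 0), all(plan$replicas >= 1))
  per_row <- plan$duration_ns * plan$replicas
  list(
    per_enzyme_ns = sum(per_row),
    total_ns = sum(per_row) * n_enzymes,
    by_type = data.frame(type = plan$type,
                         total_ns = per_row * n_enzymes)
  )
}

#' Cosolvent simulation accounting
#'
#' Per enzyme: `replicas_per_probe` replicas for each probe species, each
#' consisting of an equilibration phase and a sampling phase. With the
#' defaults (3 probes, 10 replicas each, 15 + 5 ns) this is 30 individual
#' simulations and 600 ns of simulated time per enzyme.
#'
#' @param probes probe species names.
#' @param replicas_per_probe replicas per probe, default 10.
#' @param equil_ns equilibration length per replica (ns), default 15.
#' @param sampling_ns sampling length per replica (ns), default 5.
#' @return List with `n_simulations`, `ns_per_simulation`, `total_ns`.
#' @export
cosolvent_plan <- function(probes = c("isopropanol", "acetonitrile",
                                      "pyridine"),
                           replicas_per_probe = 10,
                           equil_ns = 15, sampling_ns = 5) {
  n <- length(probes) * replicas_per_probe
  per <- equil_ns + sampling_ns
  list(n_simulations = n, ns_per_simulation = per, total_ns = n * per)
}

#' Assemble the per-enzyme outcome table
#'
#' One row per enzyme combining the metadynamics egress comparisons
#' (dissociation time and maximal potential, each labeled by the group with
#' the lower mean and annotated with its p-value) with the per-tunnel
#' bottleneck directions. `Significance` is `"yes"` when either egress
#' metric's p-value is below `alpha` — a single sub-threshold metric
#' suffices.
#'
#' @param egress named list (by enzyme) of lists with elements `delta_t`
#'   and `p_max`, each an [egress_group_compare()] result.
#' @param tunnels named list (by enzyme) of named lists (by tunnel id) of
#'   [compare_bottlenecks()] results.
#' @param enzymes enzymes to report, default the names of `egress`; every
#'   requested enzyme must be present in both inputs.
#' @param alpha significance level, default 0.1.
#' @return Data frame with columns `enzyme`, `outcome_dt`, `p_dt`,
#'   `outcome_pmax`, `p_pmax`, `significance`, and one direction column per
#'   tunnel id.
#' @export
build_outcome_table <- function(egress, tunnels, enzymes = names(egress),
                                alpha = 0.1) {
  missing_e <- setdiff(enzymes, names(egress))
  missing_t <- setdiff(enzymes, names(tunnels))
  if (length(missing_e) || length(missing_t)) {
    stop("missing enzyme(s): ",
         paste(union(missing_e, missing_t), collapse = ", "), call. = FALSE)
  }
  tunnel_ids <- sort(unique(unlist(lapply(tunnels[enzymes], names))))
  rows <- lapply(enzymes, function(e) {
    eg <- egress[[e]]
    row <- data.frame(
      enzyme = e,
      outcome_dt = eg$delta_t$label, p_dt = eg$delta_t$p,
      outcome_pmax = eg$p_max$label, p_pmax = eg$p_max$p,
      significance = if (eg$delta_t$p < alpha || eg$p_max$p < alpha)
        "yes" else "no",
      stringsAsFactors = FALSE
    )
    for (id in tunnel_ids) {
      tout <- tunnels[[e]][[id]]
      row[[paste0("r_b_", id)]] <- if (is.null(tout)) "n/a" else tout$direction
    }
    row
  })
  do.call(rbind, rows)
}
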