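test_that("bias reconstruction matches direct Gaussian summation", {
  expect_equal(bias_potential(hills_table(), 10, 100), 0)
  # single production-default hill evaluated at its own center
  h1 <- hills_table(time = 50, center = 12, width = 0.05, height = 0.03)
  expect_equal(bias_potential(h1, 12, 100), 0.03)
  # hills deposited after t are excluded
  expect_equal(bias_potential(h1, 12, 10), 0)
  # two hills one width apart: direct two-term oracle
  h2 <- hills_table(time = c(1, 2), center = c(10, 10.05),
                    width = 0.05, height = 0.03)
  expect_equal(bias_potential(h2, 10.00, 5), 0.03 * (1 + exp(-1 / 2)))
  expect_equal(bias_potential(h2, 10.05, 5), 0.03 * (1 + exp(-1 / 2)))
  # random hills: compare against an independent loop evaluation
  set.seed(3)
  hr <- hills_table(time = sort(runif(40, 0, 1000)),
                    center = runif(40, 0, 45),
                    width = runif(40, 0.03, 0.4),
                    height = runif(40, 0.01, 0.05))
  s <- runif(5, 0, 45)
  direct <- vapply(s, function(si) {
    tot <- 0
    for (i in seq_len(nrow(hr))) {
      if (hr$time[i] <= 600) {
        tot <- tot + hr$height[i] *
          exp(-(si - hr$center[i])^2 / (2 * hr$width[i]^2))
      }
    }
    tot
  }, numeric(1))
  expect_equal(bias_potential(hr, s, 600), direct)
})

test_that("bias is non-negative and non-decreasing in time", {
  set.seed(8)
  hr <- hills_table(time = sort(runif(60, 0, 500)),
                    center = runif(60, 0, 45),
                    width = runif(60, 0.05, 0.5),
                    height = runif(60, 0.01, 0.05))
  s <- runif(8, 0, 45)
  times <- seq(0, 600, by = 50)
  for (si in s) {
    v <- vapply(times, function(tt) bias_potential(hr, si, tt), numeric(1))
    expect_true(all(v >= 0))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("FWHM width convention rescales the Gaussian correctly", {
  h <- hills_table(time = 1, center = 10, width = 0.1, height = 0.03)
  # at the center the height is convention-independent
  expect_equal(bias_potential(h, 10, 5, width_is_fwhm = TRUE), 0.03)
  # at half the FWHM from the center the value is half the height
  expect_equal(bias_potential(h, 10.05, 5, width_is_fwhm = TRUE), 0.015)
})

test_that("egress detection honors threshold and persistence", {
  # never above threshold: absence is a value
  expect_true(is.na(detect_egress_time(rep(2, 50), 5, 3)))
  # clean crossing at frame 42
  s <- c(rep(2, 41), rep(8, 9))
  expect_equal(detect_egress_time(s, 5, 3), 42L)
  # hand trace: 1-frame excursion at 10, true egress at 42
  s2 <- rep(2, 60); s2[10] <- 7; s2[42:60] <- 8
  expect_equal(detect_egress_time(s2, 5, 3), 42L)
  expect_equal(detect_egress_time(s2, 5, 1), 10L)
  # run shorter than persistence at the end does not count
  s3 <- c(rep(2, 58), 8, 8)
  expect_true(is.na(detect_egress_time(s3, 5, 3)))
})

test_that("maximal potential matches brute-force dense grids", {
  # 10 identical hills at one center, evaluated after all depositions
  h <- hills_table(time = 1:10, center = 20, width = 0.05, height = 0.03)
  expect_equal(p_max(h, 100), 0.300, tolerance = 1e-6)
  # hills deposited only after the egress time contribute nothing
  expect_equal(p_max(h, 0.5), 0)
  # randomized hills vs a 10x finer grid
  for (seed in 1:5) {
    set.seed(seed)
    hr <- hills_table(time = sort(runif(50, 0, 1000)),
                      center = runif(50, 2, 43),
                      width = runif(50, 0.05, 0.6),
                      height = runif(50, 0.01, 0.05))
    spacing <- min(hr$width) / 2
    coarse <- p_max(hr, 800)
    fine_grid <- seq(0, 45, by = spacing / 10)
    fine <- max(bias_potential(hr, fine_grid, 800))
    expect_equal(coarse, fine, tolerance = 0.02)
    expect_gte(fine + 1e-12, coarse)   # the coarse grid never overshoots
  }
})

test_that("maximal potential is non-decreasing in the egress time", {
  set.seed(17)
  hr <- hills_table(time = sort(runif(40, 0, 400)),
                    center = runif(40, 0, 45),
                    width = 0.3, height = 0.03)
  v <- vapply(seq(0, 500, by = 50), function(tt) p_max(hr, tt), numeric(1))
  expect_true(all(diff(v) >= -1e-12))
})

test_that("along-trajectory variant bounds the grid maximum", {
  set.seed(23)
  hr <- hills_table(time = sort(runif(30, 0, 300)),
                    center = runif(30, 0, 30), width = 0.4, height = 0.03)
  times <- seq(0, 300, by = 10)
  cv <- runif(length(times), 0, 30)
  along <- p_max(hr, 300, cv_trace = cv, times = times)
  grid_max <- p_max(hr, 300)
  expect_lte(along, grid_max + 1e-12)
})

test_that("group comparison labels the faster-dissociating condition", {
  expect_equal(egress_group_compare(c(5, 6, 7), c(5, 6, 7))$p, 1)
  set.seed(10)
  allo <- rnorm(10, 10, 1)
  ctrl <- rnorm(10, 20, 1)
  out <- egress_group_compare(allo, ctrl)
  expect_equal(out$label, "H1")
  expect_true(out$significant)
  swapped <- egress_group_compare(ctrl, allo)
  expect_equal(swapped$label, "WAT")
  expect_equal(swapped$p, out$p)
  expect_error(egress_group_compare(1, c(1, 2)), "replicas")
})

test_that("per-replica readouts combine detection, bias and pathway", {
  h <- hills_table(time = seq(50, 5000, by = 50), center = 20,
                   width = 0.05, height = 0.03)
  md <- c(rep(2, 41), rep(8, 19))
  r <- egress_readout(md, h, frame_interval_ps = 50, persistence = 10,
                      pathway = "2f")
  expect_true(r$egressed)
  expect_equal(r$frame, 42L)
  expect_equal(r$delta_t_ns, 41 * 50 / 1000)
  # bias accumulated over the 41 hills deposited by the egress time
  expect_equal(r$p_max_kcal_mol, 41 * 0.03, tolerance = 1e-6)
  expect_equal(r$pathway, "2f")
  # non-egressing replica: evaluated at the final time and flagged
  r2 <- egress_readout(rep(2, 60), h, frame_interval_ps = 50)
  expect_false(r2$egressed)
  expect_true(is.na(r2$delta_t_ns))
  expect_equal(r2$p_max_kcal_mol, 59 * 0.03, tolerance = 1e-6)
})
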