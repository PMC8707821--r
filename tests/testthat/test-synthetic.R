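test_that("generators are deterministic under a fixed seed", {
  a <- make_membrane_system(noise_sd = 0.3, n_frames = 3, seed = 42)
  b <- make_membrane_system(noise_sd = 0.3, n_frames = 3, seed = 42)
  expect_identical(a$xyz, b$xyz)
  c <- make_membrane_system(noise_sd = 0.3, n_frames = 3, seed = 43)
  expect_false(identical(a$xyz, c$xyz))

  w1 <- make_ligand_walk(a, c(60, 0, 0), egress_frame = 2,
                         persistence_frames = 2, seed = 7)
  w2 <- make_ligand_walk(a, c(60, 0, 0), egress_frame = 2,
                         persistence_frames = 2, seed = 7)
  expect_identical(w1$xyz, w2$xyz)
})

test_that("noiseless membrane systems force the target metrics exactly", {
  for (tilt in c(0, 30, 60, 90)) {
    for (depth in c(0, 20, 37)) {
      tr <- make_membrane_system(tilt_deg = tilt, bury_depth = depth,
                                 noise_sd = 0, seed = 2)
      expect_equal(tilt_series(tr)$mean, tilt, tolerance = 1e-9)
      expect_equal(depth_series(tr)$mean, depth, tolerance = 1e-9)
      gt <- attr(tr, "ground_truth")
      expect_equal(gyration_series(tr)$mean, gt$rg, tolerance = 1e-9)
    }
  }
})

test_that("ligand walks egress at the constructed frame and direction", {
  tr <- make_membrane_system(n_frames = 60, seed = 5)
  w <- make_ligand_walk(tr, exit_anchor = c(60, 0, 0), egress_frame = 42,
                        persistence_frames = 10, seed = 5)
  md <- ligand_min_distance(w)
  expect_true(all(md[42:60] > 5))
  expect_equal(detect_egress_time(md, 5, 10), 42L)
  expect_equal(surface_crossing_frame(w), 42L)

  anchors <- list("2b" = c(-60, 0, 0), "2c" = c(0, 60, 0),
                  "2f" = c(60, 0, 0))
  com <- t(vapply(seq_len(60), function(f) {
    colMeans(frame_coords(w, f, role_indices(w$system, "LIGAND_HEAVY")))
  }, numeric(3)))
  expect_equal(classify_egress_pathway(com, anchors, 42L), "2f")
})

test_that("a single-frame excursion before egress is ignored by persistence", {
  tr <- make_membrane_system(n_frames = 60, seed = 9)
  w <- make_ligand_walk(tr, exit_anchor = c(0, -60, 0), egress_frame = 42,
                        persistence_frames = 3, seed = 9,
                        excursion_frame = 10)
  md <- ligand_min_distance(w)
  expect_true(md[10] > 5)          # the excursion really leaves
  expect_true(md[11] <= 5)         # and really returns
  expect_equal(detect_egress_time(md, 5, 3), 42L)
  # with persistence 1 the excursion itself is (wrongly) the first hit
  expect_equal(detect_egress_time(md, 5, 1), 10L)
})

test_that("alignment generator plans map onto expected matrices", {
  # all identical -> c = 1, identity = 100
  al <- make_alignment(3, 1:18, rep("identical", 18), seed = 1)
  cm <- site_conservation(al$alignment, al$site)
  expect_equal(cm$c, al$expected_c)
  expect_equal(cm$identity, al$expected_identity)
  expect_equal(unname(cm$c[1, 2]), 1.0)

  # 9 identical + 9 same-group over 18 positions -> 0.75
  al <- make_alignment(2, 1:18, rep(c("identical", "group"), each = 9),
                       seed = 2)
  cm <- site_conservation(al$alignment, al$site)
  expect_equal(unname(cm$c[1, 2]), (9 * 1 + 9 * 0.5) / 18)
  expect_equal(al$expected_c[1, 2], 0.75)

  # 15 identical + 3 different -> identity 15/18
  al <- make_alignment(2, 1:18, c(rep("identical", 15), rep("different", 3)),
                       seed = 3)
  cm <- site_conservation(al$alignment, al$site)
  expect_equal(unname(cm$identity[1, 2]), 100 * 15 / 18, tolerance = 1e-9)
  expect_equal(unname(cm$c[1, 2]), 15 / 18, tolerance = 1e-9)
})

test_that("hills schedules round trip through files", {
  f <- withr::local_tempfile(fileext = ".txt")
  # single default hill
  make_hills(data.frame(time = 0, center = 5, width = 0.05, height = 0.03), f)
  h <- read_hills(f)
  expect_equal(h$height, 0.03)
  expect_equal(h$width, 0.05)

  # long ramp keeps monotone times
  ramp <- data.frame(time = seq_len(1000), center = seq(0, 45, length.out = 1000),
                     width = 0.05, height = 0.03)
  make_hills(ramp, f)
  expect_false(is.unsorted(read_hills(f)$time))
  expect_equal(nrow(read_hills(f)), 1000)

  # empty schedule is still a readable file
  make_hills(hills_table(), f)
  expect_equal(nrow(read_hills(f)), 0)
})

test_that("tunnel-grid corridors are validated and carry known bottlenecks", {
  # corridor not reaching the boundary
  expect_error(
    make_tunnel_grid(c(7, 7, 7),
                     list(list(path = cbind(4:5, 4, 4), clearance = 2)),
                     start = c(4, 4, 4)),
    "boundary")
  # non-adjacent voxels
  expect_error(
    make_tunnel_grid(c(7, 7, 7),
                     list(list(path = rbind(c(4, 4, 4), c(6, 4, 4), c(7, 4, 4)),
                               clearance = 2)),
                     start = c(4, 4, 4)),
    "disconnected")
  tg <- make_tunnel_grid(c(7, 3, 3),
                         list(list(path = cbind(3:7, 2, 2),
                                   clearance = c(3, 2, 4, 2, 5)),
                              list(path = cbind(3:1, 2, 2),
                                   clearance = c(3, 3, 3))),
                         start = c(3, 2, 2))
  expect_equal(tg$true_bottleneck, 3)
})

test_that("ground-truth sidecars are written as JSON", {
  tr <- make_membrane_system(seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(attr(tr, "ground_truth"), f)
  gt <- jsonlite::read_json(f)
  expect_equal(gt$tilt_deg, 60)
  expect_equal(gt$bury_depth, 37)
})
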