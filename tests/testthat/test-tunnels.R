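write_caver_csv <- function(df) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, f, row.names = FALSE)
  f
}

test_that("CAVER-style profiles parse into per-tunnel series", {
  df <- expand.grid(frame = 1:10, tunnel = c("2b", "2c", "2f"))
  df$bottleneck_radius <- 1 + as.integer(factor(df$tunnel)) / 10 +
    0.01 * df$frame
  f <- write_caver_csv(df)
  series <- parse_caver_profiles(f)
  expect_named(series, c("2b", "2c", "2f"))
  expect_true(all(vapply(series, function(s) s$n, numeric(1)) == 10))
  expect_equal(series[["2b"]]$mean,
               mean(df$bottleneck_radius[df$tunnel == "2b"]))

  # tunnel absent in 4 frames: n = 6 for that series
  df2 <- df[!(df$tunnel == "2c" & df$frame <= 4), ]
  series2 <- parse_caver_profiles(write_caver_csv(df2))
  expect_equal(series2[["2c"]]$n, 6)
  expect_equal(series2[["2b"]]$n, 10)
})

test_that("malformed CAVER tables are rejected", {
  df <- data.frame(frame = c(1, 1), tunnel = c("2b", "2b"),
                   bottleneck_radius = c(1, 2))
  expect_error(parse_caver_profiles(write_caver_csv(df)), "duplicated")
  bad <- data.frame(frame = 1:3, radius_only = 1:3)
  expect_error(parse_caver_profiles(write_caver_csv(bad)), "columns")
})

test_that("bottleneck comparison reports direction, p, and absence", {
  a <- bottleneck_series("2f", rep(1.5, 10))
  expect_equal(compare_bottlenecks(a, a)$p, 1)
  expect_equal(compare_bottlenecks(a, a)$direction, "=")

  set.seed(12)
  big <- bottleneck_series("2f", rnorm(50, 2.0, 0.1))
  small <- bottleneck_series("2f", rnorm(50, 1.0, 0.1))
  out <- compare_bottlenecks(big, small)
  expect_equal(out$direction, "+")
  expect_lt(out$p, 0.1)
  # swapping the conditions flips the direction, not the p-value
  rev <- compare_bottlenecks(small, big)
  expect_equal(rev$direction, "-")
  expect_equal(rev$p, out$p)

  # tunnel absent in one condition
  empty <- bottleneck_series("2f", numeric())
  expect_equal(compare_bottlenecks(big, empty)$direction, "n/a")
  expect_equal(compare_bottlenecks(NULL, big)$direction, "n/a")
  expect_error(compare_bottlenecks(bottleneck_series("2b", 1.2), big),
               "n >= 2")
})

test_that("grid bottleneck solves corridors with known answers", {
  # single corridor, clearance profile [3, 2, 4]: bottleneck 2
  tg <- make_tunnel_grid(c(5, 3, 3),
                         list(list(path = cbind(3:5, 2, 2),
                                   clearance = c(3, 2, 4))),
                         start = c(3, 2, 2))
  res <- grid_bottleneck(tg$grid, tg$start)
  expect_true(res$found)
  expect_equal(res$bottleneck, 2)
  expect_equal(res$bottleneck, brute_maximin_paths(tg$grid$clearance,
                                                   tg$start))

  # two corridors with min clearances 1 and 2: takes the wider one
  tg2 <- make_tunnel_grid(c(5, 5, 3),
                          list(list(path = cbind(3, 3:1, 2),
                                    clearance = c(3, 1, 1)),
                               list(path = cbind(3, 3:5, 2),
                                    clearance = c(3, 2, 2))),
                          start = c(3, 3, 2))
  res2 <- grid_bottleneck(tg2$grid, tg2$start)
  expect_equal(res2$bottleneck, 2)
  expect_equal(res2$bottleneck, tg2$true_bottleneck)
  expect_equal(res2$bottleneck, brute_maximin_paths(tg2$grid$clearance,
                                                    tg2$start))
  # the returned path runs through the wider corridor
  expect_true(all(res2$path[, 2] >= 3))

  # walled-in start: a result, not an exception
  cl <- array(0, c(5, 5, 5)); cl[3, 3, 3] <- 2
  res3 <- grid_bottleneck(clearance_grid(cl), c(3, 3, 3))
  expect_false(res3$found)
  expect_true(is.na(res3$bottleneck))
  # non-positive start clearance is a usage error
  expect_error(grid_bottleneck(clearance_grid(array(0, c(3, 3, 3))),
                               c(2, 2, 2)), "clearance")
})

test_that("grid bottleneck equals the exhaustive oracle on random grids", {
  for (seed in 1:12) {
    set.seed(seed)
    dims <- c(6, 6, 4)
    cl <- array(runif(prod(dims), -0.5, 3), dim = dims)
    start <- c(3, 3, 2)
    cl[3, 3, 2] <- runif(1, 0.5, 3)
    res <- grid_bottleneck(clearance_grid(cl), start)
    oracle <- flood_maximin(cl, start)
    if (res$found) {
      expect_equal(res$bottleneck, oracle)
      # the reported path supports the reported bottleneck
      pc <- apply(res$path, 1, function(v) cl[v[1], v[2], v[3]])
      expect_equal(min(pc), res$bottleneck)
    } else {
      expect_true(is.na(oracle))
    }
  }
})

test_that("raising any voxel clearance never shrinks the bottleneck", {
  set.seed(99)
  dims <- c(5, 5, 4)
  cl <- array(runif(prod(dims), -0.5, 2), dim = dims)
  cl[3, 3, 2] <- 1.5
  base <- grid_bottleneck(clearance_grid(cl), c(3, 3, 2))$bottleneck
  for (k in 1:10) {
    v <- c(sample(5, 1), sample(5, 1), sample(4, 1))
    cl2 <- cl
    cl2[v[1], v[2], v[3]] <- cl2[v[1], v[2], v[3]] + runif(1, 0, 2)
    up <- grid_bottleneck(clearance_grid(cl2), c(3, 3, 2))$bottleneck
    expect_gte(up, base)
  }
})

test_that("egress pathway classification is nearest-anchor with ties broken", {
  com <- rbind(c(0, 0, 0), c(10, 0, 0))
  # single anchor: that id
  expect_equal(classify_egress_pathway(com, list("2c" = c(50, 0, 0)), 2L), "2c")
  # nearest anchor wins
  anchors <- list("2b" = c(-40, 0, 0), "2f" = c(14, 0, 0))
  expect_equal(classify_egress_pathway(com, anchors, 2L), "2f")
  # equidistant anchors: lexicographically smallest id
  tie <- list("2c" = c(20, 0, 0), "2b" = c(0, 0, 0))
  expect_equal(classify_egress_pathway(com, tie, 2L), "2b")
  expect_error(classify_egress_pathway(com, anchors, NA_integer_),
               "crossing")
})
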