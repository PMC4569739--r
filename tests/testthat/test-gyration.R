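# Core gyration metrics: ranking, total and k-radius, s_k, top-2 distance,
# reach curves.

test_that("rank_locations counts, orders and tie-breaks visits", {
  locs <- locations_table(c("A", "B", "C"), c(0, 1, 2), c(0, 0, 0))
  traj <- trajectories_table(rep("u", 5), 1:5, c("A", "A", "B", "A", "C"))
  p <- rank_locations(traj, locs)
  expect_equal(p$location_id, c("A", "B", "C")) # B first seen before C
  expect_equal(p$n, c(3, 1, 1))
  expect_equal(attr(p, "N"), 5)

  single <- trajectories_table("u", 1, "A")
  p1 <- rank_locations(single, locs)
  expect_equal(p1$n, 1)
  expect_equal(attr(p1, "N"), 1)

  expect_error(rank_locations(traj[0, ], locs), "empty")
  bad <- trajectories_table("u", 1, "Z")
  expect_error(rank_locations(bad, locs), "unresolvable")
})

test_that("ranks agree with an independent counting oracle", {
  set.seed(71)
  locs <- locations_table(sprintf("L%d", 1:10), runif(10), runif(10))
  ids <- sample(locs$id, 1000, replace = TRUE)
  traj <- trajectories_table(rep("u", 1000), 1:1000, ids)
  p <- rank_locations(traj, locs)
  tab <- sort(table(ids), decreasing = TRUE)
  expect_equal(sort(p$n, decreasing = TRUE), as.numeric(sort(tab, TRUE)))
  expect_equal(p$n, as.numeric(tab[p$location_id]))
})

test_that("dwell weighting uses inter-visit times and needs 2 timestamps", {
  locs <- locations_table(c("A", "B"), c(0, 1), c(0, 0))
  traj <- trajectories_table(rep("u", 3), c(0, 10, 12), c("A", "B", "A"))
  p <- rank_locations(traj, locs, weighting = "dwell")
  # A dwells 10 then gets the mean trailing dwell (6); B dwells 2
  expect_equal(p$location_id[1], "A")
  expect_equal(sum(p$n), attr(p, "N"))
  expect_gt(p$n[1], p$n[2])
  one <- trajectories_table("u", 1, "A")
  expect_error(rank_locations(one, locs, weighting = "dwell"), "dwell")
})

test_that("radius of gyration matches hand-worked values", {
  p <- worked_profile()
  expect_equal(radius_of_gyration(p), sqrt(28), tolerance = 1e-12)
  expect_equal(k_radius_of_gyration(p, 2), sqrt(8.64), tolerance = 1e-12)
  expect_equal(recurrence_ratio(p, 2), sqrt(8.64 / 28), tolerance = 1e-12)
  expect_equal(top2_distance(p), 6)
  # saturation and degenerate cases
  expect_identical(k_radius_of_gyration(p, 3), radius_of_gyration(p))
  expect_identical(k_radius_of_gyration(p, 10), radius_of_gyration(p))
  expect_equal(k_radius_of_gyration(p, 1), 0)
  expect_error(k_radius_of_gyration(p, 0), "positive")

  two <- make_traj(c(0, 10), c(0, 0), c(1, 1))
  p2 <- rank_locations(two$traj, two$locs)
  expect_equal(radius_of_gyration(p2), 5)
  expect_equal(recurrence_ratio(p2, 2), 1)

  one <- make_traj(0, 0, 5)
  p1 <- rank_locations(one$traj, one$locs)
  expect_equal(radius_of_gyration(p1), 0)
  expect_error(recurrence_ratio(p1, 2), "undefined|0")
  expect_error(top2_distance(p1), "2 distinct")
})

test_that("gyration radii agree with the direct-summation oracle", {
  set.seed(72)
  for (i in 1:1000) {
    d <- random_profile_data(sample(2:12, 1))
    tl <- make_traj(d$x, d$y, d$n)
    p <- rank_locations(tl$traj, tl$locs)
    expect_equal(radius_of_gyration(p),
                 oracle_rg(p$x, p$y, p$n), tolerance = 1e-9)
    k <- sample(seq_len(nrow(p)), 1)
    expect_equal(k_radius_of_gyration(p, k),
                 oracle_rg(p$x[1:k], p$y[1:k], p$n[1:k]), tolerance = 1e-9)
  }
})

test_that("radii are translation invariant and scale covariant", {
  set.seed(73)
  for (i in 1:25) {
    d <- random_profile_data(6)
    base <- make_traj(d$x, d$y, d$n)
    p0 <- rank_locations(base$traj, base$locs)
    shift <- make_traj(d$x + 123.4, d$y - 77.7, d$n)
    p1 <- rank_locations(shift$traj, shift$locs)
    expect_equal(radius_of_gyration(p1), radius_of_gyration(p0),
                 tolerance = 1e-9)
    expect_equal(k_radius_of_gyration(p1, 3), k_radius_of_gyration(p0, 3),
                 tolerance = 1e-9)
    expect_equal(top2_distance(p1), top2_distance(p0), tolerance = 1e-9)

    sc <- make_traj(d$x * 2.5, d$y * 2.5, d$n)
    p2 <- rank_locations(sc$traj, sc$locs)
    expect_equal(radius_of_gyration(p2), 2.5 * radius_of_gyration(p0),
                 tolerance = 1e-9)
    expect_equal(recurrence_ratio(p2, 3), recurrence_ratio(p0, 3),
                 tolerance = 1e-9)
  }
})

test_that("geographic mode uses haversine distances", {
  locs <- locations_table(c("A", "B"), c(0, 1), c(0, 0),
                          coord_mode = "geographic")
  traj <- trajectories_table(rep("u", 2), 1:2, c("A", "B"))
  p <- rank_locations(traj, locs)
  # one degree of longitude at the equator
  expect_equal(top2_distance(p), 111.19, tolerance = 1e-3)
  # r_g of two equal-weight points is half their separation
  expect_equal(radius_of_gyration(p), top2_distance(p) / 2,
               tolerance = 1e-3)
})

test_that("reach curves grow as the visit prefix grows", {
  # unit square scaled to 10 km sides, one visit per corner
  tl <- make_traj(c(0, 10, 10, 0), c(0, 0, 10, 10), c(1, 1, 1, 1))
  rc <- reach_curve(tl$traj, tl$locs, checkpoints = c(0.5, 1, 3, 4))
  expect_equal(rc$n_locations, c(0, 1, 3, 4))
  expect_equal(rc$area_km2[2], 0)
  expect_equal(rc$area_km2[4], 100)
  expect_true(all(diff(rc$n_locations) >= 0))
  expect_true(all(diff(rc$area_km2) >= 0))

  set.seed(74)
  d <- random_profile_data(20)
  counts <- rep(1, 20)
  tl2 <- make_traj(d$x, d$y, counts)
  ord <- sample(nrow(tl2$traj))
  traj2 <- trajectories_table(tl2$traj$individual_id,
                              seq_along(ord), tl2$traj$location_id[ord])
  rc2 <- reach_curve(traj2, tl2$locs, checkpoints = c(5, 10, 20))
  for (i in seq_len(nrow(rc2))) {
    pref <- traj2[traj2$timestamp <= rc2$t[i], ]
    li <- match(unique(pref$location_id), tl2$locs$id)
    expect_equal(rc2$area_km2[i],
                 oracle_hull_area(tl2$locs$x[li], tl2$locs$y[li]),
                 tolerance = 1e-9)
  }
  expect_true(all(diff(rc2$n_locations) >= 0))
  expect_true(all(diff(rc2$area_km2) >= -1e-12))
})

test_that("population profiles match the per-individual functions", {
  set.seed(75)
  d1 <- random_profile_data(5)
  d2 <- random_profile_data(9)
  t1 <- make_traj(d1$x, d1$y, d1$n, ind = "u1")
  t2 <- make_traj(d2$x, d2$y, d2$n, ind = "u2")
  locs <- locations_table(c(paste0("a", t1$locs$id), paste0("b", t2$locs$id)),
                          c(t1$locs$x, t2$locs$x), c(t1$locs$y, t2$locs$y))
  traj <- trajectories_table(
    c(t1$traj$individual_id, t2$traj$individual_id),
    c(t1$traj$timestamp, t2$traj$timestamp),
    c(paste0("a", t1$traj$location_id), paste0("b", t2$traj$location_id)))
  prof <- gyration_profiles(traj, locs, k_max = 6)

  p1 <- rank_locations(traj[traj$individual_id == "u1", ], locs)
  expect_equal(prof$r_g[prof$individual_id == "u1"],
               radius_of_gyration(p1), tolerance = 1e-12)
  expect_equal(prof$rg_k3[prof$individual_id == "u1"],
               k_radius_of_gyration(p1, 3), tolerance = 1e-12)
  expect_equal(prof$s_k4[prof$individual_id == "u1"],
               recurrence_ratio(p1, 4), tolerance = 1e-12)
  expect_equal(prof$top2_distance[prof$individual_id == "u1"],
               top2_distance(p1), tolerance = 1e-12)
  # exact saturation at k >= n_locations
  expect_identical(prof$s_k5[prof$individual_id == "u1"], 1)
  expect_identical(prof$s_k6[prof$individual_id == "u1"], 1)
})
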