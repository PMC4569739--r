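# Returner/explorer classification and population curves.

test_that("bisector rule splits at s_k = 0.5 with ties to returner", {
  expect_equal(bisector_classify(c(1, 0, 0.5555, 0.5, 0.4999)),
               c("returner", "explorer", "returner", "returner", "explorer"))
  expect_error(bisector_classify(c(0.7, NA)), "unclassifiable")
  # the worked three-location profile sits just above the bisector
  p <- worked_profile()
  expect_equal(bisector_classify(recurrence_ratio(p, 2)), "returner")
})

test_that("EM clustering agrees with the bisector on separated modes", {
  set.seed(91)
  s <- c(pmax(rnorm(500, 0.05, 0.04), 0), pmin(rnorm(500, 0.95, 0.04), 1.3))
  em <- em_classify(s)
  expect_gte(mean(em$labels == bisector_classify(s)), 0.99)
  # planted component means recovered
  expect_lt(abs(em$means[1] - 0.05), 0.05)
  expect_lt(abs(em$means[2] - 0.95), 0.05)
  # deterministic: same input, same output
  expect_identical(em_classify(s), em)
  expect_warning(em_classify(rep(1, 50)), "degenerate")
  expect_error(em_classify(rnorm(5)), ">= 10")
})

test_that("EM matches an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(92)
  s <- c(rnorm(400, 0.1, 0.05), rnorm(600, 0.85, 0.07))
  em <- em_classify(s)
  mc <- mclust::Mclust(s, G = 2, modelNames = "V", verbose = FALSE)
  mc_lab <- ifelse(mc$classification == which.max(mc$parameters$mean),
                   "returner", "explorer")
  expect_gte(mean(em$labels == mc_lab), 0.99)
  expect_equal(sort(em$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("balance curve crosses 0.5 where expected", {
  # everyone visits exactly two locations: returners from k = 2 on
  set.seed(93)
  rows <- lapply(1:20, function(i) {
    d <- random_profile_data(2)
    tl <- make_traj(d$x, d$y, d$n, ind = sprintf("u%02d", i))
    list(traj = tl$traj, locs = tl$locs, i = i)
  })
  locs <- locations_table(
    unlist(lapply(rows, function(r) paste0(r$i, "_", r$locs$id))),
    unlist(lapply(rows, function(r) r$locs$x)),
    unlist(lapply(rows, function(r) r$locs$y)))
  traj <- trajectories_table(
    unlist(lapply(rows, function(r) r$traj$individual_id)),
    unlist(lapply(rows, function(r) r$traj$timestamp)),
    unlist(lapply(rows, function(r) paste0(r$i, "_", r$traj$location_id))))
  prof <- gyration_profiles(traj, locs, k_max = 4)
  bc <- balance_curve(prof)
  expect_equal(bc$returner_fraction, rep(1, 3))
  expect_equal(attr(bc, "balance_k"), 2)

  # planted explorers: almost no returners at k = 2, all returners at the
  # population's maximum location count
  gen <- generate_archetypes(0, 200, seed = 94)
  prof2 <- gyration_profiles(gen$trajectories, gen$locations, k_max = 30)
  bc2 <- balance_curve(prof2)
  expect_lt(bc2$returner_fraction[bc2$k == 2], 0.05)
  expect_equal(bc2$returner_fraction[bc2$k == 30], 1)
})

test_that("classify_population drops degenerate individuals and labels", {
  gen <- generate_archetypes(50, 50, seed = 95)
  prof <- gyration_profiles(gen$trajectories, gen$locations, k_max = 4)
  lab <- classify_population(prof, k = 2)
  expect_setequal(unique(lab$label), c("returner", "explorer"))
  truth <- gen$labels$label[match(lab$individual_id,
                                  gen$labels$individual_id)]
  expect_gte(mean(lab$label == truth), 0.95)
  expect_error(classify_population(prof, k = 99), "k_max")
})

test_that("top-2 distance correlates with r_g more for returners", {
  prof <- tibble::tibble(individual_id = sprintf("u%d", 1:12),
                         r_g = 1:12,
                         top2_distance = (1:12) * 2)
  lab <- tibble::tibble(individual_id = prof$individual_id,
                        label = "returner")
  expect_equal(top2_correlation(prof, lab)$pearson_r, 1)

  set.seed(96)
  n <- 10000
  prof2 <- tibble::tibble(individual_id = sprintf("u%d", 1:n),
                          r_g = runif(n), top2_distance = runif(n))
  lab2 <- tibble::tibble(individual_id = prof2$individual_id,
                         label = "explorer")
  expect_lt(abs(top2_correlation(prof2, lab2)$pearson_r), 0.05)

  const <- tibble::tibble(individual_id = sprintf("u%d", 1:5),
                          r_g = 1:5, top2_distance = rep(1, 5))
  labc <- tibble::tibble(individual_id = const$individual_id,
                         label = "returner")
  expect_error(top2_correlation(const, labc), "constant")

  # archetypes: returner top-2 distance tracks r_g, explorer does not
  gen <- generate_archetypes(300, 300, seed = 97)
  prof3 <- gyration_profiles(gen$trajectories, gen$locations, k_max = 4)
  cors <- top2_correlation(prof3, gen$labels)
  r_ret <- cors$pearson_r[cors$label == "returner"]
  r_exp <- cors$pearson_r[cors$label == "explorer"]
  expect_gt(r_ret, r_exp)
  expect_gt(r_ret, 0.9)
})

test_that("explorers become returners as k grows, not the other way", {
  sim <- epr_simulate(epr_config(n_agents = 200, n_events = 300, seed = 98))
  prof <- gyration_profiles(sim$trajectories, sim$locations, k_max = 40)
  smat <- as.matrix(prof[, paste0("s_k", 2:40)])
  lab <- smat >= 0.5
  flips <- lab[, -1] != lab[, -ncol(lab)]
  rev_flips <- lab[, -ncol(lab)] & !lab[, -1] # returner -> explorer
  # forward transitions dominate; model trajectories keep some jitter
  # around the bisector so the reverse direction is a small minority
  expect_lt(sum(rev_flips) / max(sum(flips), 1), 0.2)
  # and the population curve rises monotonically with k
  frac <- colMeans(lab)
  expect_true(all(diff(frac) > -1e-12))
})
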