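# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (direct summation, gift-wrapping hull, pairwise edge
# scan) and must never call the implementation they check.

# direct evaluation of the weighted gyration radius
oracle_rg <- function(x, y, n) {
  N <- sum(n)
  cx <- sum(n * x) / N
  cy <- sum(n * y) / N
  acc <- 0
  for (i in seq_along(x)) {
    acc <- acc + n[i] * ((x[i] - cx)^2 + (y[i] - cy)^2)
  }
  sqrt(acc / N)
}

# convex hull area by gift wrapping (Jarvis march) + shoelace
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  m <- nrow(pts)
  if (m < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == m) 1L else p + 1L
    for (r in seq_len(m)) {
      if (r == p) next
      cr <- cross(pts[p, ], pts[q, ], pts[r, ])
      if (cr < 0) q <- r
    }
    p <- q
    if (p == start || length(hull) > m) break
  }
  if (length(hull) < 3) return(0)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  j <- c(seq_along(hull)[-1], 1)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

# undirected edge set of consecutive-distinct trips, one trajectory at a
# time, by explicit scanning
oracle_edges <- function(traj) {
  out <- character(0)
  for (id in unique(traj$individual_id)) {
    sub <- traj[traj$individual_id == id, ]
    sub <- sub[order(sub$timestamp), ]
    locs <- sub$location_id
    if (length(locs) < 2) next
    for (i in seq_len(length(locs) - 1)) {
      a <- locs[i]; b <- locs[i + 1]
      if (a == b) next
      out <- c(out, paste(min(a, b), max(a, b), sep = "--"))
    }
  }
  sort(unique(out))
}

# random visit profile on the plane (ranked by the implementation later)
random_profile_data <- function(n_loc, weight_max = 20) {
  list(x = runif(n_loc, -50, 50), y = runif(n_loc, -50, 50),
       n = sample.int(weight_max, n_loc, replace = TRUE))
}

# build a one-individual trajectory + location table from coords/counts
make_traj <- function(x, y, counts, ind = "u1") {
  ids <- sprintf("L%02d", seq_along(x))
  locs <- locations_table(ids, x, y)
  visit_ids <- rep(ids, counts)
  traj <- trajectories_table(rep(ind, length(visit_ids)),
                             seq_along(visit_ids), visit_ids)
  list(traj = traj, locs = locs)
}

# the worked three-location profile used in several places:
# (0,0) weight 3, (6,0) weight 2, (0,12) weight 1 -> r_g = sqrt(28)
worked_profile <- function() {
  locs <- locations_table(c("A", "B", "C"), c(0, 6, 0), c(0, 0, 12))
  traj <- trajectories_table(rep("u", 6), 1:6,
                             c("A", "A", "A", "B", "B", "C"))
  rank_locations(traj, locs)
}
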