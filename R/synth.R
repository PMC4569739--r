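# Synthetic fixtures: relevance landscapes, planted returner/explorer
# archetype trajectories, and call graphs with planted same-class
# preference. These emulate the qualitative structure of CDR/GPS mobility
# data (heavy-tailed location relevance, the two-class geometry of
# recurrent mobility, class-assortative communication) without reproducing
# any proprietary data set.

#' Generate a random relevance landscape
#'
#' Locations uniformly scattered over a square of side `extent_km`;
#' relevances follow a Zipf rank-law, `relevance of rank r` proportional to
#' `r^-zipf_exponent`, assigned to locations in random order (exponent 0
#' gives equal relevances). This mimics the heavy-tailed distribution of
#' calls placed from cell towers.
#'
#' @param n_locations number of locations (>= 2).
#' @param extent_km side of the square (km), default 250.
#' @param zipf_exponent Zipf exponent (default 1).
#' @param seed integer seed.
#' @return a planar `locations` tibble.
#' @export
generate_landscape <- function(n_locations, extent_km = 250,
                               zipf_exponent = 1, seed = 1) {
  stopifnot(n_locations >= 2, extent_km > 0, zipf_exponent >= 0)
  set.seed(seed)
  rel <- (seq_len(n_locations))^(-zipf_exponent)
  rel <- sample(rel) / max(rel)
  locations_table(id = sprintf("s%d", seq_len(n_locations)),
                  x = runif(n_locations, 0, extent_km),
                  y = runif(n_locations, 0, extent_km),
                  relevance = rel, coord_mode = "planar")
}

#' Generate planted returner/explorer archetype trajectories
#'
#' Returner archetype: two dominant locations (home/work) separated by
#' about twice the target radius of gyration, each surrounded by a tight
#' satellite cluster; the top-2 carry `top2_share` of all visits, so
#' `s_2` is close to 1. Explorer archetype: the two dominant locations sit
#' close together near the centre while low-frequency satellites lie far
#' away (at about `r_g / sqrt(1 - top2_share)` from the centre), so the
#' total radius is dominated by rarely visited places and `s_2` is close
#' to 0.
#'
#' Per-individual target radii are drawn from a truncated power law
#' (defaults mirror heavy-tailed empirical radii). With `landscape = NULL`
#' every individual gets private continuous planar locations (noise-free
#' recovery tests); with a landscape, generated points are snapped to the
#' nearest landscape location (shared-grid mode for network experiments).
#'
#' @param n_returners,n_explorers archetype counts.
#' @param n_visits visits per individual (default 60).
#' @param n_locations_returner,n_locations_explorer distinct locations per
#'   archetype (defaults 10 and 30: explorers wander among more places).
#' @param top2_share share of visits on the two dominant locations
#'   (default 0.8).
#' @param spread_ratio satellite-cluster scale relative to the target
#'   radius (default 0.1).
#' @param r_g_law [tpl()] law for per-individual target radii (km).
#' @param landscape optional `locations` tibble to snap onto.
#' @param seed integer seed.
#' @return a list: `trajectories`, `locations`, `labels` (tibble
#'   `individual_id, label` of planted ground truth).
#' @export
generate_archetypes <- function(n_returners, n_explorers, n_visits = 60,
                                n_locations_returner = 10,
                                n_locations_explorer = 30,
                                top2_share = 0.8, spread_ratio = 0.1,
                                r_g_law = tpl(r0 = 5.5, alpha = 1.6,
                                              r_cut = 250.11, r_min = 2),
                                landscape = NULL, seed = 1) {
  stopifnot(n_returners >= 0, n_explorers >= 0,
            n_returners + n_explorers >= 1,
            top2_share > 0, top2_share < 1, n_visits >= 4)
  set.seed(seed)
  n_ind <- n_returners + n_explorers
  labels <- rep(c("returner", "explorer"), c(n_returners, n_explorers))
  rg_t <- tpl_sample(r_g_law, n_ind)

  if (!is.null(landscape)) {
    extent <- c(range(landscape$x), range(landscape$y))
  }

  traj_id <- vector("list", n_ind)
  traj_loc <- vector("list", n_ind)
  priv_x <- vector("list", n_ind)
  priv_y <- vector("list", n_ind)

  for (i in seq_len(n_ind)) {
    rg <- rg_t[i]
    nl <- if (labels[i] == "returner") n_locations_returner
          else n_locations_explorer
    nsat <- nl - 2L
    theta <- runif(1, 0, 2 * pi)
    u <- c(cos(theta), sin(theta))
    centre <- if (is.null(landscape)) c(0, 0) else {
      c(runif(1, extent[1], extent[2]), runif(1, extent[3], extent[4]))
    }
    if (labels[i] == "returner") {
      anchors <- rbind(centre + rg * u, centre - rg * u)
      host <- sample.int(2, nsat, replace = TRUE)
      sat <- anchors[host, , drop = FALSE] +
        matrix(rnorm(2 * nsat, 0, spread_ratio * rg), ncol = 2)
    } else {
      eps <- spread_ratio * rg / 2
      anchors <- rbind(centre + eps * u, centre - eps * u)
      d_far <- rg / sqrt(1 - top2_share)
      ang <- runif(nsat, 0, 2 * pi)
      rad <- d_far * (1 + rnorm(nsat, 0, 0.15))
      sat <- cbind(centre[1] + rad * cos(ang), centre[2] + rad * sin(ang))
    }
    pts <- rbind(anchors, sat)
    w <- c(top2_share * c(0.58, 0.42),
           rep((1 - top2_share) / nsat, nsat))
    seq_i <- sample.int(nl, n_visits, replace = TRUE, prob = w)
    # dominant-rank guarantee: force anchors into the first visits
    seq_i[1:2] <- 1:2

    if (is.null(landscape)) {
      traj_id[[i]] <- seq_i
      priv_x[[i]] <- pts[, 1]
      priv_y[[i]] <- pts[, 2]
    } else {
      snapped <- snap_to(pts, landscape)
      traj_id[[i]] <- snapped[seq_i]
    }
  }

  ind <- sprintf("i%d", rep(seq_len(n_ind), each = n_visits))
  ts <- rep(seq_len(n_visits), n_ind)
  if (is.null(landscape)) {
    nls <- lengths(priv_x)
    locs <- locations_table(
      id = sprintf("i%d_L%d", rep(seq_len(n_ind), nls),
                   unlist(lapply(nls, seq_len))),
      x = unlist(priv_x), y = unlist(priv_y), coord_mode = "planar")
    loc_id <- sprintf("i%d_L%d", rep(seq_len(n_ind), each = n_visits),
                      unlist(traj_id))
  } else {
    locs <- landscape
    loc_id <- landscape$id[unlist(traj_id)]
  }
  traj <- trajectories_table(ind, ts, loc_id)
  list(trajectories = traj, locations = locs,
       labels = tibble::tibble(individual_id = sprintf("i%d", seq_len(n_ind)),
                               label = labels))
}

# nearest landscape location for each row of a 2-column point matrix
snap_to <- function(pts, landscape) {
  vapply(seq_len(nrow(pts)), function(j) {
    which.min((landscape$x - pts[j, 1])^2 + (landscape$y - pts[j, 2])^2)
  }, integer(1))
}

#' Generate a call graph with planted class homophily
#'
#' Each individual gets `contacts_per_individual` ranked contacts. For
#' every contact slot, with probability `pi` the partner is drawn from the
#' individual's own mobility class, otherwise uniformly from the whole
#' population, so the same-class probability is
#' `pi + (1 - pi) * marginal`. Call counts decrease strictly with rank.
#'
#' @param labels a tibble `individual_id, label`.
#' @param pi same-class preference in `[0, 1]`.
#' @param contacts_per_individual ranked contacts per caller (default 5).
#' @param seed integer seed.
#' @return a call-graph tibble.
#' @export
generate_call_graph <- function(labels, pi = 0.3,
                                contacts_per_individual = 5, seed = 1) {
  stopifnot(pi >= 0, pi <= 1, contacts_per_individual >= 1)
  set.seed(seed)
  ids <- labels$individual_id
  cls <- labels$label
  n <- length(ids)
  if (pi > 0 && any(table(cls) < 2)) {
    stop("need at least 2 individuals per class when pi > 0", call. = FALSE)
  }
  m <- contacts_per_individual
  if (m > n - 1) {
    stop("contacts_per_individual exceeds the number of possible partners",
         call. = FALSE)
  }
  if (pi == 1 && any(table(cls) <= m)) {
    stop("pi = 1 requires more than contacts_per_individual members per class",
         call. = FALSE)
  }
  by_class <- split(seq_len(n), cls)

  caller <- character(n * m)
  callee <- character(n * m)
  row <- 0L
  for (i in seq_len(n)) {
    own <- by_class[[cls[i]]]
    picked <- integer(0)
    for (r in seq_len(m)) {
      repeat {
        pool <- if (runif(1) < pi) own else seq_len(n)
        j <- pool[sample.int(length(pool), 1L)]
        if (j != i && !(j %in% picked)) break
      }
      picked <- c(picked, j)
      row <- row + 1L
      caller[row] <- ids[i]
      callee[row] <- ids[j]
    }
  }
  call_graph_table(caller, callee,
                   call_count = rep(2 * (m:1), n))
}
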