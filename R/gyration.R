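# Recurrence-aware gyration statistics.
#
# The total radius of gyration of an individual is
#   r_g = sqrt( (1/N) * sum_i n_i * |r_i - r_cm|^2 ),
#   r_cm = (1/N) * sum_i n_i * r_i,
# where n_i is the visitation frequency (or total dwell time) at location i
# and N = sum_i n_i. The k-radius r_g^(k) applies the same formula to the k
# most frequented locations only, with their own centre of mass and weight
# sum N_k, and the recurrence ratio s_k = r_g^(k) / r_g measures how much of
# an individual's overall mobility is carried by recurrent visits.

#' Rank the locations of one individual's trajectory
#'
#' Builds the visit profile: locations sorted by descending weight (visit
#' counts by default, or total dwell time), ties broken by earlier first
#' visit and then by lexicographic id.
#'
#' @param traj a `trajectories` tibble for a single individual.
#' @param locations a `locations` tibble resolving every visited id.
#' @param weighting `"counts"` (visitation frequency, the CDR convention)
#'   or `"dwell"` (time spent before the next displacement; the final visit
#'   is weighted by the mean dwell of the preceding ones so that every
#'   visited location keeps positive weight).
#' @return a `visit_profile` tibble with columns `location_id, x, y, n,
#'   first_seen`, attributes `individual_id`, `N` and `coord_mode`.
#' @export
rank_locations <- function(traj, locations,
                           weighting = c("counts", "dwell")) {
  weighting <- match.arg(weighting)
  check_trajectories(traj, locations)
  if (length(unique(traj$individual_id)) != 1) {
    stop("rank_locations() expects the trajectory of a single individual",
         call. = FALSE)
  }
  ord <- order(traj$timestamp)
  ids <- traj$location_id[ord]
  ts <- as.numeric(traj$timestamp[ord])

  if (weighting == "counts") {
    w <- rep(1, length(ids))
  } else {
    if (length(ts) < 2) {
      stop("dwell weighting requires at least 2 timestamped visits",
           call. = FALSE)
    }
    d <- diff(ts)
    if (any(d < 0)) stop("timestamps must be non-decreasing", call. = FALSE)
    w <- c(d, mean(d))
    w[w <= 0] <- min(w[w > 0], 1e-9) # co-timed visits keep a token weight
  }

  first_pos <- !duplicated(ids)
  uniq <- ids[first_pos]
  grp <- match(ids, uniq)
  n <- as.numeric(tapply(w, grp, sum))
  fs <- ts[first_pos]
  o <- order(-n, fs, uniq)

  li <- match(uniq[o], locations$id)
  out <- tibble::tibble(location_id = uniq[o],
                        x = locations$x[li], y = locations$y[li],
                        n = n[o], first_seen = fs[o])
  attr(out, "individual_id") <- traj$individual_id[1]
  attr(out, "N") <- sum(n)
  attr(out, "coord_mode") <- coord_mode_of(locations)
  class(out) <- c("visit_profile", class(out))
  out
}

# Weighted gyration radius of a km-plane point set.
rg_km <- function(xy, n) {
  N <- sum(n)
  cx <- sum(n * xy[, 1]) / N
  cy <- sum(n * xy[, 2]) / N
  sqrt(sum(n * ((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)) / N)
}

#' Total radius of gyration
#'
#' Weighted root-mean-square distance of the visited locations from the
#' individual's centre of mass, in km. Geographic coordinates are first
#' projected to a local km plane about the weighted mean lon/lat.
#'
#' @param profile a `visit_profile` from [rank_locations()].
#' @return radius of gyration in km.
#' @export
radius_of_gyration <- function(profile) {
  xy <- project_km(profile$x, profile$y, profile$n, coord_mode_of(profile))
  rg_km(xy, profile$n)
}

#' k-radius of gyration
#'
#' The radius of gyration computed over the k most frequented locations
#' only, with their own centre of mass and weight sum. For
#' `k >= nrow(profile)` it equals the total radius exactly.
#'
#' @inheritParams radius_of_gyration
#' @param k number of top-ranked locations, `>= 1`.
#' @return k-radius of gyration in km.
#' @export
k_radius_of_gyration <- function(profile, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  xy <- project_km(profile$x, profile$y, profile$n, coord_mode_of(profile))
  k <- min(k, nrow(profile))
  rg_km(xy[seq_len(k), , drop = FALSE], profile$n[seq_len(k)])
}

#' Recurrence ratio s_k
#'
#' `s_k = r_g^(k) / r_g`: near 1 when the k most frequented locations carry
#' the individual's overall mobility (a k-returner), near 0 when they do
#' not (a k-explorer). Can exceed 1 for the few individuals whose top-k
#' locations are farther from the centre of mass than the rest.
#'
#' @inheritParams k_radius_of_gyration
#' @return dimensionless ratio.
#' @export
recurrence_ratio <- function(profile, k) {
  rg <- radius_of_gyration(profile)
  if (rg == 0) {
    stop("recurrence ratio undefined: total radius of gyration is 0",
         call. = FALSE)
  }
  k_radius_of_gyration(profile, k) / rg
}

#' Distance between the two most frequented locations
#'
#' @inheritParams radius_of_gyration
#' @return distance L1 to L2 in km (haversine for geographic mode).
#' @export
top2_distance <- function(profile) {
  if (nrow(profile) < 2) {
    stop("top2_distance needs at least 2 distinct locations", call. = FALSE)
  }
  dist_km(profile$x[1], profile$y[1], profile$x[2], profile$y[2],
          coord_mode_of(profile))
}

#' Trajectory reach over time
#'
#' Splits a mobility history at the given checkpoints and reports, for the
#' visit prefix up to each time `t`: the number of distinct locations, the
#' convex-hull area of the visited coordinates (km^2), and the total radius
#' of gyration r_g(t). Checkpoints preceding the first visit yield zeros.
#'
#' @param traj a single individual's `trajectories` tibble.
#' @param locations a `locations` tibble.
#' @param checkpoints sorted numeric timestamps.
#' @return a tibble with columns `t, n_locations, area_km2, r_g`.
#' @export
reach_curve <- function(traj, locations, checkpoints) {
  check_trajectories(traj, locations)
  stopifnot(!is.unsorted(checkpoints))
  ord <- order(traj$timestamp)
  ts <- as.numeric(traj$timestamp[ord])
  li <- match(traj$location_id[ord], locations$id)
  mode <- coord_mode_of(locations)

  rows <- lapply(checkpoints, function(t) {
    sel <- ts <= t
    if (!any(sel)) {
      return(c(n_locations = 0, area_km2 = 0, r_g = 0))
    }
    idx <- li[sel]
    n <- tabulate(match(idx, unique(idx)))
    ux <- locations$x[unique(idx)]
    uy <- locations$y[unique(idx)]
    xy <- project_km(ux, uy, n, mode)
    c(n_locations = length(unique(idx)),
      area_km2 = hull_area_km2(xy[, 1], xy[, 2]),
      r_g = rg_km(xy, n))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$t <- as.numeric(checkpoints)
  out[, c("t", "n_locations", "area_km2", "r_g")]
}

#' Gyration profiles for a population
#'
#' Computes, for every individual in a trajectory set: the number of
#' distinct locations, total radius of gyration, the distance between the
#' two most frequented locations, and the k-radii `rg_k2..rg_k<k_max>` with
#' their recurrence ratios `s_k2..s_k<k_max>`. For `k` at or beyond an
#' individual's location count the k-radius saturates at the total radius
#' (`s_k = 1` exactly). Individuals with a single location have `r_g = 0`
#' and `NA` ratios.
#'
#' @param traj a `trajectories` tibble (any number of individuals).
#' @param locations a `locations` tibble.
#' @param k_max largest k reported (default 10).
#' @param weighting passed to [rank_locations()].
#' @return a tibble, one row per individual.
#' @export
gyration_profiles <- function(traj, locations, k_max = 10,
                              weighting = c("counts", "dwell")) {
  weighting <- match.arg(weighting)
  check_trajectories(traj, locations)
  stopifnot(k_max >= 2, k_max <= 200)
  mode <- coord_mode_of(locations)
  li_all <- match(traj$location_id, locations$id)

  per_ind <- function(ts, li) {
    ord <- order(ts)
    ts <- as.numeric(ts[ord]); li <- li[ord]
    if (weighting == "counts") {
      w <- rep(1, length(li))
    } else {
      d <- diff(ts)
      w <- if (length(d) == 0) 1 else c(d, mean(d))
      w[w <= 0] <- if (any(w > 0)) min(w[w > 0]) else 1
    }
    first_pos <- !duplicated(li)
    uniq <- li[first_pos]
    n <- as.numeric(tapply(w, match(li, uniq), sum))
    o <- order(-n, ts[first_pos], locations$id[uniq])
    uniq <- uniq[o]; n <- n[o]
    L <- length(uniq)

    xy <- project_km(locations$x[uniq], locations$y[uniq], n, mode)
    # cumulative top-k second moments: all k-radii in one pass
    cn <- cumsum(n)
    sx <- cumsum(n * xy[, 1]); sy <- cumsum(n * xy[, 2])
    sq <- cumsum(n * (xy[, 1]^2 + xy[, 2]^2))
    rgk <- sqrt(pmax(0, sq / cn - (sx^2 + sy^2) / cn^2))
    rg <- rgk[L]

    ks <- 2:k_max
    rg_cols <- rgk[pmin(ks, L)]
    s_cols <- if (rg > 0) rg_cols / rg else rep(NA_real_, length(ks))
    s_cols[ks >= L] <- if (rg > 0) 1 else NA_real_
    rg_cols[ks >= L] <- rg
    d12 <- if (L >= 2) {
      dist_km(locations$x[uniq[1]], locations$y[uniq[1]],
              locations$x[uniq[2]], locations$y[uniq[2]], mode)
    } else NA_real_
    c(L, sum(n), rg, d12, rg_cols, s_cols)
  }

  groups <- split(seq_len(nrow(traj)), traj$individual_id)
  mat <- vapply(groups, function(ix) per_ind(traj$timestamp[ix], li_all[ix]),
                numeric(4 + 2 * (k_max - 1)))
  mat <- t(mat)
  out <- tibble::tibble(individual_id = names(groups))
  base_names <- c("n_locations", "N", "r_g", "top2_distance")
  kn <- 2:k_max
  colnames(mat) <- c(base_names, paste0("rg_k", kn), paste0("s_k", kn))
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  attr(out, "k_max") <- k_max
  attr(out, "coord_mode") <- mode
  out
}
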