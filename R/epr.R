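# Exploration and preferential return (EPR) simulators.
#
# At every displacement event an agent that has already visited S distinct
# locations explores a new location with probability
#   P_new = rho * S^(-gamma)
# and otherwise returns to a previously visited location chosen with
# probability proportional to its visit frequency. The classic EPR agent
# explores on the free plane: it jumps a distance drawn from a truncated
# power law in a uniformly random direction. The gravity-augmented d-EPR
# agent instead picks a never-visited location j of a fixed landscape with
# probability proportional to relevance_j / d(i, j)^exponent from its
# current location i, which confines trajectories to the landscape.
#
# Preferential return is implemented by sampling a uniformly random past
# visit and moving to its location — exactly proportional to visit counts
# in O(1) per event. The current location can be redrawn (a self-return),
# matching frequency-proportional return over all visited locations.

#' EPR / d-EPR simulation configuration
#'
#' Defaults follow the standard EPR parameterisation: exploration
#' probability `rho * S^-gamma` with `rho = 0.6`, `gamma = 0.21`; jump
#' lengths from the canonical displacement law `(dr + 1.5 km)^-1.75 *
#' exp(-dr/10^4 km)` — the planetary-scale cutoff leaves free-space agents able to
#' travel essentially arbitrary distances, the behaviour the
#' landscape-constrained d-EPR variant corrects; waiting times (hours)
#' from `dt^-(1+0.8) * exp(-dt/17 h)` bounded below at 0.2 h. All are
#' configurable.
#'
#' @param n_agents number of synthetic individuals.
#' @param n_events number of displacement events per agent.
#' @param rho exploration scale in `[0, 1]`.
#' @param gamma exploration exponent `>= 0`.
#' @param jump_law a [tpl()] object for jump lengths (km); EPR only.
#' @param wait_law a [tpl()] object for waiting times (hours).
#' @param gravity_exponent distance-deterrence exponent of the d-EPR
#'   exploration kernel (power-law deterrence).
#' @param seed integer seed; every simulation is reproducible from it.
#' @return an `epr_config` list.
#' @export
epr_config <- function(n_agents = 1000, n_events = 200,
                       rho = 0.6, gamma = 0.21,
                       jump_law = tpl(r0 = 1.5, alpha = 1.75, r_cut = 1e4),
                       wait_law = tpl(r0 = 0, alpha = 1.8, r_cut = 17,
                                      r_min = 0.2),
                       gravity_exponent = 2, seed = 1) {
  stopifnot(rho >= 0, rho <= 1, gamma >= 0, n_events >= 1, n_agents >= 1,
            inherits(jump_law, "tpl"), inherits(wait_law, "tpl"))
  structure(list(n_agents = n_agents, n_events = n_events, rho = rho,
                 gamma = gamma, jump_law = jump_law, wait_law = wait_law,
                 gravity_exponent = gravity_exponent, seed = seed),
            class = "epr_config")
}

#' Simulate EPR trajectories on the free plane
#'
#' @param config an [epr_config()].
#' @return a list: `trajectories` (tibble `individual_id, timestamp,
#'   location_id` with timestamps in cumulative hours), `locations` (planar
#'   `locations` tibble of every location created by exploration).
#' @export
epr_simulate <- function(config) {
  stopifnot(inherits(config, "epr_config"))
  set.seed(config$seed)
  n_ev <- config$n_events
  n_ag <- config$n_agents

  all_ids <- vector("list", n_ag)
  all_ts <- vector("list", n_ag)
  loc_x <- vector("list", n_ag)
  loc_y <- vector("list", n_ag)

  for (a in seq_len(n_ag)) {
    jumps <- tpl_sample(config$jump_law, n_ev)
    angles <- runif(n_ev, 0, 2 * pi)
    waits <- tpl_sample(config$wait_law, n_ev)
    u_exp <- runif(n_ev)
    u_ret <- runif(n_ev)
    visits <- integer(n_ev + 1)
    lx <- numeric(n_ev + 1)
    ly <- numeric(n_ev + 1)
    visits[1] <- 1L
    S <- 1L
    cur <- 1L
    for (t in seq_len(n_ev)) {
      if (u_exp[t] < config$rho * S^(-config$gamma)) {
        S <- S + 1L
        lx[S] <- lx[cur] + jumps[t] * cos(angles[t])
        ly[S] <- ly[cur] + jumps[t] * sin(angles[t])
        cur <- S
      } else {
        cur <- visits[1L + floor(u_ret[t] * t)]
      }
      visits[t + 1L] <- cur
    }
    all_ids[[a]] <- visits
    all_ts[[a]] <- c(0, cumsum(waits))
    loc_x[[a]] <- lx[seq_len(S)]
    loc_y[[a]] <- ly[seq_len(S)]
  }

  agent <- rep(seq_len(n_ag), each = n_ev + 1)
  loc_id <- sprintf("a%d_L%d", agent, unlist(all_ids))
  traj <- tibble::tibble(individual_id = sprintf("a%d", agent),
                         timestamp = unlist(all_ts),
                         location_id = loc_id)
  ns <- lengths(loc_x)
  locs <- locations_table(
    id = sprintf("a%d_L%d", rep(seq_len(n_ag), ns),
                 unlist(lapply(ns, seq_len))),
    x = unlist(loc_x), y = unlist(loc_y),
    coord_mode = "planar")
  list(trajectories = traj, locations = locs)
}

#' Gravity exploration probabilities
#'
#' Probability of a trip from `origin` to each candidate location of the
#' landscape: proportional to `relevance_j / d(origin, j)^exponent`,
#' normalised over the candidates (the origin and any excluded, e.g.
#' already-visited, locations get probability 0).
#'
#' @param landscape a `locations` tibble with positive relevances.
#' @param origin index (or id) of the origin location.
#' @param excluded indices (or ids) to exclude besides the origin.
#' @param exponent distance-deterrence exponent (default 2).
#' @return a probability vector over the landscape rows.
#' @export
gravity_probabilities <- function(landscape, origin, excluded = integer(0),
                                  exponent = 2) {
  if (is.character(origin)) origin <- match(origin, landscape$id)
  if (is.character(excluded)) excluded <- match(excluded, landscape$id)
  w <- gravity_row(landscape, origin, exponent)
  w[excluded] <- 0
  tot <- sum(w)
  if (tot <= 0) {
    stop("empty support: no candidate location has positive probability",
         call. = FALSE)
  }
  w / tot
}

# unnormalised gravity weights from one origin; small LRU-ish cache
gravity_row <- function(landscape, origin, exponent) {
  key <- paste0("grav|", attr(landscape, "hash"), "|", origin, "|", exponent)
  cached <- !is.null(attr(landscape, "hash"))
  if (cached) {
    hit <- .retex_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  d <- dist_km(landscape$x[origin], landscape$y[origin],
               landscape$x, landscape$y, coord_mode_of(landscape))
  w <- landscape$relevance / pmax(d, 1e-9)^exponent
  w[origin] <- 0
  if (cached && length(ls(.retex_cache)) < 4000) .retex_cache[[key]] <- w
  w
}

#' Simulate d-EPR trajectories on a relevance landscape
#'
#' Identical to [epr_simulate()] except that exploration draws a
#' never-visited landscape location from the gravity kernel of the current
#' position, and agents start at locations sampled proportionally to
#' relevance. When an agent has visited every location and an exploration
#' is drawn, it falls back to a preferential return (counted in the
#' returned `forced_returns`).
#'
#' @param config an [epr_config()].
#' @param landscape a `locations` tibble (>= 2 locations, relevances >= 0
#'   with at least two positive).
#' @return a list: `trajectories`, `locations` (the landscape), and
#'   `forced_returns` (count of exploration draws with no unvisited
#'   candidate).
#' @export
depr_simulate <- function(config, landscape) {
  stopifnot(inherits(config, "epr_config"), nrow(landscape) >= 2,
            sum(landscape$relevance > 0) >= 2)
  set.seed(config$seed)
  n_ev <- config$n_events
  n_ag <- config$n_agents
  n_loc <- nrow(landscape)
  expo <- config$gravity_exponent

  # per-origin cumulative gravity weights, cached for the duration of this
  # simulation (agents share origins heavily, so hit rates are high);
  # exploration uses inverse-CDF draws with rejection of already-visited
  # targets, falling back to exact masked sampling when rejection stalls.
  cum_cache <- new.env(parent = emptyenv())
  cache_n <- 0L
  cum_row <- function(origin) {
    key <- as.character(origin)
    hit <- cum_cache[[key]]
    if (!is.null(hit)) return(hit)
    d2 <- (landscape$x - landscape$x[origin])^2 +
      (landscape$y - landscape$y[origin])^2
    w <- landscape$relevance / pmax(sqrt(d2), 1e-9)^expo
    w[origin] <- 0
    cw <- cumsum(w)
    if (cache_n < 3500L) {
      cum_cache[[key]] <- cw
      cache_n <<- cache_n + 1L
    }
    cw
  }
  if (coord_mode_of(landscape) == "geographic") {
    # project once to a local km plane; adequate for country-scale gravity
    xy <- project_km(landscape$x, landscape$y, coord_mode = "geographic")
    landscape$x <- xy[, 1]
    landscape$y <- xy[, 2]
  }

  starts <- sample.int(n_loc, n_ag, replace = TRUE,
                       prob = landscape$relevance)
  all_ids <- vector("list", n_ag)
  all_ts <- vector("list", n_ag)
  forced <- 0L

  for (a in seq_len(n_ag)) {
    waits <- tpl_sample(config$wait_law, n_ev)
    u_exp <- runif(n_ev)
    u_ret <- runif(n_ev)
    visits <- integer(n_ev + 1)
    visited <- logical(n_loc)
    cur <- starts[a]
    visits[1] <- cur
    visited[cur] <- TRUE
    S <- 1L
    for (t in seq_len(n_ev)) {
      explore <- u_exp[t] < config$rho * S^(-config$gamma)
      if (explore && S < n_loc) {
        cw <- cum_row(cur)
        tot <- cw[n_loc]
        # acceptance probability of a rejection draw = unvisited mass share
        vis_idx <- visits[seq_len(t)]
        vis_idx <- vis_idx[!duplicated(vis_idx)]
        prev <- vis_idx - 1L
        v_mass <- sum(cw[vis_idx]) - sum(cw[prev[prev > 0L]])
        acc <- 1 - v_mass / tot
        nxt <- 0L
        if (is.finite(acc) && acc > 0.05) {
          repeat {
            j <- findInterval(runif(1) * tot, cw) + 1L
            if (!visited[j]) { nxt <- j; break }
          }
        } else { # exact masked draw on nearly exhausted support
          w <- c(cw[1], diff(cw))
          w[visited] <- 0
          if (sum(w) > 0) nxt <- sample.int(n_loc, 1L, prob = w)
        }
        if (nxt > 0L) {
          cur <- nxt
          visited[cur] <- TRUE
          S <- S + 1L
        } else {
          forced <- forced + 1L
          cur <- visits[1L + floor(u_ret[t] * t)]
        }
      } else {
        if (explore) forced <- forced + 1L
        cur <- visits[1L + floor(u_ret[t] * t)]
      }
      visits[t + 1L] <- cur
    }
    all_ids[[a]] <- visits
    all_ts[[a]] <- c(0, cumsum(waits))
  }

  agent <- rep(seq_len(n_ag), each = n_ev + 1)
  traj <- tibble::tibble(individual_id = sprintf("a%d", agent),
                         timestamp = unlist(all_ts),
                         location_id = landscape$id[unlist(all_ids)])
  list(trajectories = traj, locations = landscape, forced_returns = forced)
}
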