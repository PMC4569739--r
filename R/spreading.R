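# Global mobility networks and the metapopulation global invasion
# threshold.
#
# The global mobility network has locations as nodes and an undirected
# edge wherever at least one trip (a pair of consecutive distinct visited
# locations in some trajectory) was observed. For a metapopulation with
# uncorrelated degree distribution, homogeneous per-capita diffusion rate
# p, subpopulation size N_bar, recovery rate mu and reproductive number R0
# close to 1, the branching-process global invasion threshold is
#
#   R* = (<k^2> - <k>)/<k>^2 * 2 (R0 - 1)^2 / R0^2 * p N_bar / mu ,
#
# and an epidemic can invade the system only if R* > 1. The first factor
# is the degree-heterogeneity term: the more heterogeneous the network's
# degrees, the lower the barrier to global invasion.

#' Build the global mobility network from trajectories
#'
#' Every pair of consecutive distinct locations visited in a trajectory
#' contributes one trip. Edges are undirected and deduplicated; the trip
#' count is kept as the edge attribute `trips`. Locations with no trips do
#' not enter the network.
#'
#' @param traj a `trajectories` tibble.
#' @param populations optional named vector of resident populations per
#'   location id (default 1), stored as the vertex attribute `population`.
#' @return an `igraph` undirected graph.
#' @export
build_global_network <- function(traj, populations = NULL) {
  check_trajectories(traj)
  ord <- order(traj$individual_id, traj$timestamp)
  ind <- traj$individual_id[ord]
  loc <- traj$location_id[ord]
  same_ind <- ind[-1] == ind[-length(ind)]
  from <- loc[-length(loc)]
  to <- loc[-1]
  keep <- same_ind & from != to
  # collapse runs of repeated locations: a->a->b is one a-b trip
  from <- from[keep]
  to <- to[keep]
  if (length(from) == 0) stop("no trips: empty mobility network",
                              call. = FALSE)
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      trips = as.numeric(tab))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  pop <- rep(1, igraph::vcount(g))
  if (!is.null(populations)) {
    hit <- match(igraph::V(g)$name, names(populations))
    pop[!is.na(hit)] <- populations[hit[!is.na(hit)]]
  }
  igraph::V(g)$population <- pop
  g
}

#' Invasion-threshold parameters
#'
#' Defaults target the regime of large subpopulations and a reproductive
#' number close to the epidemic threshold: `R0 = 1.1`, recovery rate
#' `mu = 0.2` per day, per-capita travel rate `p = 1e-3`, reference
#' subpopulation size `N_bar = 10000`.
#'
#' @param R0 basic reproductive number (> 0).
#' @param mu recovery rate (1/days).
#' @param p per-capita diffusion (travel) rate in `(0, 1]`.
#' @param N_bar reference subpopulation size (>= 1).
#' @return an `invasion_params` list.
#' @export
invasion_params <- function(R0 = 1.1, mu = 0.2, p = 1e-3, N_bar = 1e4) {
  stopifnot(R0 > 0, mu > 0, p > 0, p <= 1, N_bar >= 1)
  structure(list(R0 = R0, mu = mu, p = p, N_bar = N_bar),
            class = "invasion_params")
}

# degree-heterogeneity factor (<k^2> - <k>) / <k>^2 from a degree vector
degree_heterogeneity <- function(deg) {
  (mean(deg^2) - mean(deg)) / mean(deg)^2
}

# threshold prefactor isolated so alternative conventions are a one-line
# change: R* = heterogeneity * 2 (R0-1)^2 / R0^2 * p N_bar / mu
r_star_from_moments <- function(het, params) {
  if (params$R0 <= 1) return(0)
  het * 2 * (params$R0 - 1)^2 / params$R0^2 *
    params$p * params$N_bar / params$mu
}

#' Global invasion threshold R*
#'
#' @param network an `igraph` graph from [build_global_network()] (>= 2
#'   nodes, >= 1 edge).
#' @param params an [invasion_params()] object.
#' @return a list: `R_star`, `heterogeneity` (the degree-moment factor),
#'   `mean_degree`. `R0 <= 1` returns `R_star = 0`: no supercritical
#'   branching process exists.
#' @export
invasion_threshold <- function(network, params = invasion_params()) {
  stopifnot(inherits(network, "igraph"), inherits(params, "invasion_params"))
  if (igraph::vcount(network) < 2 || igraph::ecount(network) < 1) {
    stop("invasion threshold needs >= 2 nodes and >= 1 edge", call. = FALSE)
  }
  deg <- igraph::degree(network, loops = FALSE)
  het <- degree_heterogeneity(deg)
  list(R_star = r_star_from_moments(het, params),
       heterogeneity = het, mean_degree = mean(deg))
}

#' Mixed returner/explorer population spreading experiment
#'
#' For each explorer fraction f on the grid, repeatedly samples
#' `sample_size` individuals (`round(f * sample_size)` explorers, the rest
#' returners, without replacement within class), builds the global mobility
#' network of the sample, and computes R*. Mirrors the construction of
#' mobility networks from random populations with varying class mix.
#'
#' @param traj a `trajectories` tibble covering the pool.
#' @param labels tibble `individual_id, label` for the pool.
#' @param explorer_fractions fraction grid (default `seq(0, 1, 0.1)`).
#' @param sample_size individuals per network (default 1000).
#' @param n_reps networks per fraction (default 100).
#' @param params an [invasion_params()] object.
#' @param seed integer seed.
#' @return a list: `summary` (tibble `explorer_fraction, mean_R_star,
#'   sd_R_star, mean_heterogeneity`), `R_star` (matrix n_reps x fractions).
#' @export
mixed_population_experiment <- function(traj, labels,
                                        explorer_fractions = seq(0, 1, 0.1),
                                        sample_size = 1000, n_reps = 100,
                                        params = invasion_params(),
                                        seed = 1) {
  stopifnot(n_reps >= 1, sample_size >= 2)
  set.seed(seed)
  ret_ids <- labels$individual_id[labels$label == "returner"]
  exp_ids <- labels$individual_id[labels$label == "explorer"]

  need_exp <- max(round(explorer_fractions * sample_size))
  need_ret <- max(round((1 - explorer_fractions) * sample_size))
  if (length(exp_ids) < need_exp || length(ret_ids) < need_ret) {
    stop(sprintf(
      "insufficient pool: need up to %d explorers (have %d) and %d returners (have %d)",
      need_exp, length(exp_ids), need_ret, length(ret_ids)), call. = FALSE)
  }

  edge_sets <- individual_edge_codes(traj)
  n_loc <- attr(edge_sets, "n_locations")

  rs <- matrix(NA_real_, n_reps, length(explorer_fractions))
  hets <- matrix(NA_real_, n_reps, length(explorer_fractions))
  for (j in seq_along(explorer_fractions)) {
    f <- explorer_fractions[j]
    ne <- round(f * sample_size)
    nr <- sample_size - ne
    for (r in seq_len(n_reps)) {
      pick <- c(if (nr > 0) sample(ret_ids, nr),
                if (ne > 0) sample(exp_ids, ne))
      codes <- unique(unlist(edge_sets[pick], use.names = FALSE))
      i1 <- codes %% n_loc
      i2 <- codes %/% n_loc
      deg <- tabulate(c(i1, i2) + 1L, nbins = n_loc)
      deg <- deg[deg > 0]
      hets[r, j] <- degree_heterogeneity(deg)
      rs[r, j] <- r_star_from_moments(hets[r, j], params)
    }
  }
  list(summary = tibble::tibble(
         explorer_fraction = explorer_fractions,
         mean_R_star = colMeans(rs),
         sd_R_star = apply(rs, 2, sd),
         mean_heterogeneity = colMeans(hets)),
       R_star = rs)
}

# per-individual sets of undirected edge codes (i + j * n_loc, i < j)
individual_edge_codes <- function(traj) {
  ord <- order(traj$individual_id, traj$timestamp)
  ind <- traj$individual_id[ord]
  loc_f <- match(traj$location_id[ord], unique(traj$location_id[ord])) - 1L
  n_loc <- max(loc_f) + 1L
  same <- ind[-1] == ind[-length(ind)]
  from <- loc_f[-length(loc_f)]
  to <- loc_f[-1]
  keep <- same & from != to
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  code <- a + as.numeric(b) * n_loc
  out <- lapply(split(code, ind[-1][keep]), unique)
  attr(out, "n_locations") <- n_loc
  out
}
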