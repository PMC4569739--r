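# Tabular data model and CSV readers/writers.
#
# locations:    tibble(id, x, y, relevance) with attribute coord_mode
#               ("planar": x/y in km; "geographic": x = lon, y = lat degrees)
# trajectories: tibble(individual_id, timestamp, location_id), timestamps
#               non-decreasing within individual (numeric hours or POSIXct)
# call graph:   tibble(caller_id, callee_id, call_count)

#' Build a location table
#'
#' @param id character location identifiers (unique).
#' @param x,y coordinates: lon/lat degrees (geographic) or km (planar).
#' @param relevance nonnegative weights (e.g. total calls placed from the
#'   location); defaults to 1.
#' @param coord_mode `"planar"` or `"geographic"`.
#' @return a `locations` tibble.
#' @export
locations_table <- function(id, x, y, relevance = 1,
                            coord_mode = c("planar", "geographic")) {
  coord_mode <- match.arg(coord_mode)
  id <- as.character(id)
  stopifnot(!anyDuplicated(id), all(is.finite(x)), all(is.finite(y)),
            all(relevance >= 0))
  if (coord_mode == "geographic" && (any(y < -90) || any(y > 90))) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  out <- tibble::tibble(id = id, x = as.numeric(x), y = as.numeric(y),
                        relevance = rep_len(as.numeric(relevance), length(id)))
  attr(out, "coord_mode") <- coord_mode
  out
}

coord_mode_of <- function(x, default = "planar") {
  m <- attr(x, "coord_mode")
  if (is.null(m)) default else m
}

#' Assemble a trajectory table
#'
#' @param individual_id,timestamp,location_id parallel vectors of visits.
#' @return a `trajectories` tibble sorted by individual and time.
#' @export
trajectories_table <- function(individual_id, timestamp, location_id) {
  stopifnot(length(individual_id) > 0)
  out <- tibble::tibble(individual_id = as.character(individual_id),
                        timestamp = timestamp,
                        location_id = as.character(location_id))
  out[order(out$individual_id, out$timestamp), ]
}

check_trajectories <- function(traj, locations = NULL) {
  stopifnot(all(c("individual_id", "timestamp", "location_id") %in%
                  names(traj)))
  if (nrow(traj) == 0) stop("empty trajectory set", call. = FALSE)
  if (!is.null(locations)) {
    missing <- setdiff(unique(traj$location_id), locations$id)
    if (length(missing) > 0) {
      stop(sprintf("unresolvable location id(s): %s",
                   paste(head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(traj)
}

#' Read trajectories from CSV
#'
#' Two dialects are supported, selected from the header:
#' `individual_id,timestamp,location_id` (visits reference a location
#' table) or `individual_id,timestamp,lon,lat` (coordinates inline; a
#' geographic location table is derived from the distinct coordinates).
#' Timestamps are parsed as ISO-8601 UTC when not numeric.
#'
#' @param path CSV file path.
#' @param strict if `TRUE` (default) unparseable timestamps abort with the
#'   offending line number; if `FALSE` such rows are dropped with a warning.
#' @return a `trajectories` tibble; for the lon/lat dialect the derived
#'   location table is attached as attribute `"locations"`.
#' @export
read_trajectories <- function(path, strict = TRUE) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_id <- all(c("individual_id", "timestamp", "location_id") %in% names(df))
  has_ll <- all(c("individual_id", "timestamp", "lon", "lat") %in% names(df))
  if (!has_id && !has_ll) {
    stop("unrecognised trajectory CSV dialect: need columns ",
         "individual_id,timestamp,location_id or individual_id,timestamp,lon,lat",
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("trajectory file contains a header but no rows")
    return(tibble::tibble(individual_id = character(),
                          timestamp = numeric(),
                          location_id = character()))
  }
  ts <- parse_timestamps(df$timestamp, strict)
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    if (strict) {
      stop(sprintf("unparseable timestamp at line %d: '%s'",
                   bad[1] + 1L, df$timestamp[bad[1]]), call. = FALSE)
    }
    warning(sprintf("dropped %d row(s) with unparseable timestamps",
                    length(bad)))
    df <- df[-bad, , drop = FALSE]
    ts <- ts[-bad]
  }
  if (has_id) {
    return(trajectories_table(df$individual_id, ts, df$location_id))
  }
  key <- paste(df$lon, df$lat, sep = "|")
  uniq <- !duplicated(key)
  locs <- locations_table(id = paste0("loc", seq_len(sum(uniq))),
                          x = df$lon[uniq], y = df$lat[uniq],
                          coord_mode = "geographic")
  out <- trajectories_table(df$individual_id, ts,
                            locs$id[match(key, key[uniq])])
  attr(out, "locations") <- locs
  out
}

parse_timestamps <- function(ts, strict = TRUE) {
  if (is.numeric(ts)) return(ts)
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
  out <- rep(as.POSIXct(NA), length(ts))
  for (f in fmts) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- suppressWarnings(as.POSIXct(ts[todo], tz = "UTC", format = f))
  }
  out
}

#' Write trajectories to CSV
#' @param traj a `trajectories` tibble.
#' @param path output path.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj[, c("individual_id", "timestamp", "location_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a location table from CSV (`id,lon,lat,relevance` or
#' `id,x,y,relevance`)
#' @param path CSV file path.
#' @return a `locations` tibble.
#' @export
read_locations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("id", "lon", "lat") %in% names(df))) {
    locations_table(df$id, df$lon, df$lat,
                    relevance = if ("relevance" %in% names(df)) df$relevance else 1,
                    coord_mode = "geographic")
  } else if (all(c("id", "x", "y") %in% names(df))) {
    locations_table(df$id, df$x, df$y,
                    relevance = if ("relevance" %in% names(df)) df$relevance else 1,
                    coord_mode = "planar")
  } else {
    stop("location CSV needs columns id,lon,lat[,relevance] or id,x,y[,relevance]",
         call. = FALSE)
  }
}

#' Write a location table to CSV
#' @param locations a `locations` tibble.
#' @param path output path.
#' @export
write_locations <- function(locations, path) {
  df <- locations
  if (coord_mode_of(locations) == "geographic") {
    names(df)[match(c("x", "y"), names(df))] <- c("lon", "lat")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a call graph from CSV (`caller_id,callee_id,call_count`)
#' @param path CSV file path.
#' @return a call-graph tibble.
#' @export
read_call_graph <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("caller_id", "callee_id", "call_count") %in% names(df)))
  call_graph_table(df$caller_id, df$callee_id, df$call_count)
}

#' Assemble a call-graph table
#' @param caller_id,callee_id,call_count parallel edge vectors.
#' @return a call-graph tibble (directed weighted edges, no self-edges).
#' @export
call_graph_table <- function(caller_id, callee_id, call_count) {
  out <- tibble::tibble(caller_id = as.character(caller_id),
                        callee_id = as.character(callee_id),
                        call_count = as.numeric(call_count))
  stopifnot(all(out$call_count >= 1))
  if (any(out$caller_id == out$callee_id)) {
    stop("self-edges are not allowed in a call graph", call. = FALSE)
  }
  out
}

#' Write a population profile table to CSV
#'
#' One row per individual: `individual_id,n_locations,r_g,rg_k2..,s_k2..`.
#' @param profiles output of [gyration_profiles()].
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
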