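# Splitting a population into k-returners and k-explorers.
#
# The bisector rule classifies an individual as a k-returner when the
# k most frequented locations carry at least half of the overall mobility
# range, i.e. 2 * r_g^(k) >= r_g (s_k >= 0.5); k-explorer otherwise. The
# EM alternative fits a two-component Gaussian mixture to the population's
# s_k values and labels the higher-mean component "returner".

#' Bisector classification
#'
#' @param s_k numeric vector of recurrence ratios.
#' @return character vector `"returner"` / `"explorer"`. Ties
#'   (`s_k == 0.5` exactly) are returners. `NA` ratios (individuals with
#'   `r_g = 0`) raise an error: such degenerate single-location individuals
#'   must be filtered out upstream.
#' @export
bisector_classify <- function(s_k) {
  if (any(is.na(s_k))) {
    stop("unclassifiable individual: s_k is NA (r_g = 0)", call. = FALSE)
  }
  ifelse(s_k >= 0.5, "returner", "explorer")
}

#' Two-component Gaussian-mixture EM classification
#'
#' Fits a two-component univariate Gaussian mixture to the population's
#' s_k values by expectation-maximisation and labels each individual by the
#' posterior-dominant component; the component with the higher mean is the
#' returner class. Initialisation is deterministic: component means start
#' at the 25th and 75th percentiles, equal weights, common within-sample
#' standard deviation, so identical input always yields identical output.
#'
#' @param s_values numeric vector of s_k ratios (>= 10 finite values).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return a list: `labels` (character), `means`, `sds`, `weights` (mixture
#'   parameters, returner component second), `posterior` (returner
#'   probability), `loglik`, `degenerate` flag.
#' @export
em_classify <- function(s_values, max_iter = 500, tol = 1e-8) {
  x <- s_values
  if (length(x) < 10 || any(!is.finite(x))) {
    stop("em_classify needs >= 10 finite s_k values", call. = FALSE)
  }
  if (sd(x) < 1e-12) {
    warning("degenerate population: all s_k equal; single cluster")
    lab <- bisector_classify(x)
    return(list(labels = lab, means = rep(mean(x), 2), sds = c(0, 0),
                weights = c(0, 1), posterior = rep(1, length(x)),
                loglik = NA_real_, degenerate = TRUE))
  }
  mu <- as.numeric(quantile(x, c(0.25, 0.75)))
  sg <- rep(sd(x) / 2, 2)
  pi2 <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi2[1] * dnorm(x, mu[1], max(sg[1], 1e-6))
    d2 <- pi2[2] * dnorm(x, mu[2], max(sg[2], 1e-6))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g2 <- d2 / tot
    g1 <- 1 - g2
    pi2 <- c(mean(g1), mean(g2))
    mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
    sg <- sqrt(c(sum(g1 * (x - mu[1])^2) / sum(g1),
                 sum(g2 * (x - mu[2])^2) / sum(g2)))
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  # returner = higher-mean component, reported second
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); pi2 <- rev(pi2); g2 <- 1 - g2
  }
  list(labels = ifelse(g2 >= 0.5, "returner", "explorer"),
       means = mu, sds = sg, weights = pi2, posterior = g2,
       loglik = ll, degenerate = FALSE)
}

#' Classify a population at a given k
#'
#' @param profiles a [gyration_profiles()] tibble.
#' @param k which k-radius to classify on (default 2).
#' @param method `"bisector"` or `"em"`.
#' @return a tibble `individual_id, k, label, s_k`. Individuals with
#'   `r_g = 0` (single location) are dropped with a message, mirroring the
#'   usual filter that retains users visiting more than 2 locations.
#' @export
classify_population <- function(profiles, k = 2,
                                method = c("bisector", "em")) {
  method <- match.arg(method)
  col <- paste0("s_k", k)
  if (!col %in% names(profiles)) {
    stop(sprintf("profiles table has no column %s; recompute with k_max >= %d",
                 col, k), call. = FALSE)
  }
  s <- profiles[[col]]
  keep <- !is.na(s)
  if (any(!keep)) {
    message(sprintf("dropping %d individual(s) with r_g = 0", sum(!keep)))
  }
  lab <- if (method == "bisector") {
    bisector_classify(s[keep])
  } else {
    em_classify(s[keep])$labels
  }
  tibble::tibble(individual_id = profiles$individual_id[keep],
                 k = k, label = lab, s_k = s[keep])
}

#' Returner fraction as a function of k
#'
#' For each k in `2..k_max`, the fraction of the (classifiable) population
#' that the bisector rule labels k-returner. The balance point is the
#' smallest k at which the fraction reaches 0.5; a linearly interpolated
#' crossing between the bracketing integers is reported alongside.
#'
#' @param profiles a [gyration_profiles()] tibble computed with
#'   `k_max >=` the requested `k_max`.
#' @param k_max largest k scanned (default: the profiles' own k_max).
#' @return a tibble `k, returner_fraction` with attributes `balance_k`
#'   (integer crossing, `NA` when never reached) and `balance_k_interp`.
#' @export
balance_curve <- function(profiles, k_max = attr(profiles, "k_max")) {
  stopifnot(!is.null(k_max), k_max >= 2)
  ks <- 2:k_max
  frac <- vapply(ks, function(k) {
    s <- profiles[[paste0("s_k", k)]]
    if (is.null(s)) stop(sprintf("profiles lack s_k%d", k), call. = FALSE)
    s <- s[!is.na(s)]
    mean(s >= 0.5)
  }, numeric(1))
  out <- tibble::tibble(k = ks, returner_fraction = frac)
  cross <- which(frac >= 0.5)
  balance_k <- if (length(cross) == 0) NA_integer_ else ks[cross[1]]
  balance_interp <- NA_real_
  if (!is.na(balance_k)) {
    i <- cross[1]
    if (i == 1 || frac[i] == 0.5) {
      balance_interp <- as.numeric(ks[i])
      if (i > 1 && frac[i] > 0.5) balance_interp <- interp_cross(ks, frac, i)
    } else {
      balance_interp <- interp_cross(ks, frac, i)
    }
  }
  attr(out, "balance_k") <- balance_k
  attr(out, "balance_k_interp") <- balance_interp
  out
}

interp_cross <- function(ks, frac, i) {
  if (i == 1) return(as.numeric(ks[1]))
  k0 <- ks[i - 1]; k1 <- ks[i]
  f0 <- frac[i - 1]; f1 <- frac[i]
  if (f1 == f0) return(as.numeric(k1))
  k0 + (0.5 - f0) / (f1 - f0) * (k1 - k0)
}

#' Correlation of top-2 distance with total radius, per class
#'
#' For returners the distance between the two most frequented locations
#' grows with the total radius of gyration; for explorers it stays small.
#' This computes the Pearson correlation within each class.
#'
#' @param profiles a [gyration_profiles()] tibble.
#' @param labels a classification tibble from [classify_population()].
#' @return a tibble `label, n, pearson_r`.
#' @export
top2_correlation <- function(profiles, labels) {
  df <- dplyr::inner_join(
    profiles[, c("individual_id", "r_g", "top2_distance")],
    labels[, c("individual_id", "label")], by = "individual_id")
  df <- df[is.finite(df$r_g) & is.finite(df$top2_distance), ]
  res <- lapply(split(df, df$label), function(g) {
    if (nrow(g) < 3) {
      stop("need at least 3 individuals per class for a correlation",
           call. = FALSE)
    }
    if (sd(g$r_g) == 0 || sd(g$top2_distance) == 0) {
      stop("undefined correlation: constant vector within a class",
           call. = FALSE)
    }
    tibble::tibble(label = g$label[1], n = nrow(g),
                   pearson_r = cor(g$r_g, g$top2_distance))
  })
  dplyr::bind_rows(res)
}
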