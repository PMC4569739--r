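# Mobility-class assortativity of communication ties.
#
# Observed quantities: among classified returners who have an n-th most
# called contact with a known class, RR is the fraction whose n-th contact
# is also a returner (RE = 1 - RR); EE and ER likewise for explorers. The
# null model randomly reassigns the n-th-contact vector across individuals
# (preserving the multiset of named friends, hence the class marginals),
# and one-sided empirical p-values use the add-one estimator
# p = (1 + #{null >= observed}) / (n_perm + 1) for RR and EE (<= for
# RE and ER).

#' n-th most called contact of every caller
#'
#' Contacts are ranked per caller by descending call count; ties are
#' broken by descending reciprocal calls (callee back to caller), then by
#' lexicographic callee id. Callers with fewer than `n` contacts are
#' absent from the result.
#'
#' @param graph a call-graph tibble (`caller_id, callee_id, call_count`).
#' @param n friendship rank (>= 1).
#' @return a tibble `individual_id, friend_id`.
#' @export
nth_best_friend <- function(graph, n = 1) {
  stopifnot(n >= 1)
  recip_key <- paste(graph$callee_id, graph$caller_id, sep = "\r")
  fwd_key <- paste(graph$caller_id, graph$callee_id, sep = "\r")
  recip <- graph$call_count[match(recip_key, fwd_key)]
  recip[is.na(recip)] <- 0
  o <- order(graph$caller_id, -graph$call_count, -recip, graph$callee_id)
  caller <- graph$caller_id[o]
  rank <- stats::ave(seq_along(caller), caller, FUN = seq_along)
  sel <- rank == n
  tibble::tibble(individual_id = caller[sel],
                 friend_id = graph$callee_id[o][sel])
}

#' Observed class fractions of n-th best friendships
#'
#' @param graph a call-graph tibble.
#' @param labels tibble `individual_id, label` of mobility classes.
#' @param n friendship rank.
#' @return a list: `fractions` (named RR, RE, ER, EE), `n_pairs` (number
#'   of classified caller/friend pairs used), `n_excluded` (pairs dropped
#'   because caller or friend is unclassified), `marginal_returner` (share
#'   of returners among named friends). Pairs whose caller or friend lacks
#'   a label are excluded symmetrically from observed and null statistics.
#' @export
class_fractions <- function(graph, labels, n = 1) {
  bf <- nth_best_friend(graph, n)
  ic <- labels$label[match(bf$individual_id, labels$individual_id)]
  fc <- labels$label[match(bf$friend_id, labels$individual_id)]
  keep <- !is.na(ic) & !is.na(fc)
  res <- fractions_from_classes(ic[keep], fc[keep])
  res$n_pairs <- sum(keep)
  res$n_excluded <- sum(!keep)
  res
}

fractions_from_classes <- function(ic, fc) {
  iR <- ic == "returner"
  fR <- fc == "returner"
  n_ret <- sum(iR)
  n_exp <- sum(!iR)
  if (n_ret == 0 || n_exp == 0) {
    warning("no eligible returners or explorers: fractions undefined")
  }
  RR <- if (n_ret > 0) mean(fR[iR]) else NA_real_
  EE <- if (n_exp > 0) mean(!fR[!iR]) else NA_real_
  list(fractions = c(RR = RR, RE = 1 - RR, ER = 1 - EE, EE = EE),
       marginal_returner = mean(fR))
}

#' Permutation test for mobility-class homophily
#'
#' Compares the observed RR/RE/ER/EE fractions at friendship rank `n`
#' against a null in which the n-th-friend assignment vector is randomly
#' permuted across individuals. `n_perm` randomisations; one-sided
#' add-one p-values (RR, EE tested high; RE, ER tested low).
#'
#' @inheritParams class_fractions
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return a list: `observed` (fractions), `p_values`, `null_mean`,
#'   `null_sd`, `marginal_returner`, `n_pairs`, `n_perm`.
#' @export
reassignment_test <- function(graph, labels, n = 1, n_perm = 1000,
                              seed = 1) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  bf <- nth_best_friend(graph, n)
  ic <- labels$label[match(bf$individual_id, labels$individual_id)]
  fc <- labels$label[match(bf$friend_id, labels$individual_id)]
  keep <- !is.na(ic) & !is.na(fc)
  ic <- ic[keep]
  fc <- fc[keep]
  if (length(ic) < 2) stop("too few classified pairs", call. = FALSE)

  obs <- fractions_from_classes(ic, fc)
  iR <- ic == "returner"
  fR <- fc == "returner"
  null_RR <- numeric(n_perm)
  null_EE <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- fR[sample.int(length(fR))]
    null_RR[b] <- mean(perm[iR])
    null_EE[b] <- mean(!perm[!iR])
  }
  p <- c(
    RR = (1 + sum(null_RR >= obs$fractions["RR"])) / (n_perm + 1),
    RE = (1 + sum(1 - null_RR <= obs$fractions["RE"])) / (n_perm + 1),
    ER = (1 + sum(1 - null_EE <= obs$fractions["ER"])) / (n_perm + 1),
    EE = (1 + sum(null_EE >= obs$fractions["EE"])) / (n_perm + 1))
  list(observed = obs$fractions,
       p_values = p,
       null_mean = c(RR = mean(null_RR), RE = mean(1 - null_RR),
                     ER = mean(1 - null_EE), EE = mean(null_EE)),
       null_sd = c(RR = sd(null_RR), EE = sd(null_EE)),
       marginal_returner = obs$marginal_returner,
       n_pairs = length(ic), n_perm = n_perm)
}
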