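# Node-level reconfiguration statistics on community trajectories.
#
# At each transition t -> t+1 a node either keeps its label or changes it.
# Changing nodes are grouped by their (source, destination) label pair:
# a group of size >= 2 is one cohesive event (the nodes moved together),
# a group of size 1 is one disjoint event (the node moved alone). Every
# change belongs to exactly one event, which is what makes
# flexibility = disjointedness + cohesive change rate an identity.

.check_traj <- function(traj) {
  stopifnot(inherits(traj, "community_trajectory"))
  if (n_layers(traj) < 2) {
    stop("need at least 2 layers (T >= 2) to score transitions",
         call. = FALSE)
  }
}

.match_rule <- function(rule) match.arg(rule, c("pair", "dest-only"))

#' Classify every community switch as cohesive or disjoint
#'
#' Scans all `T - 1` transitions of a community trajectory. Nodes whose label
#' changes at a transition are grouped into events: under the default
#' `"pair"` rule nodes co-switch only if they make the same
#' source-to-destination move; under `"dest-only"` any nodes arriving in the
#' same destination community together co-switch regardless of origin.
#'
#' A community that splits (one group of its members leaves together) or
#' merges into another produces cohesive events and no disjoint ones.
#'
#' @param traj a [community_trajectory()].
#' @param rule `"pair"` (default) or `"dest-only"`.
#' @return a tibble with one row per event: `transition` (t, the move happens
#'   between layers t and t+1), `source`, `destination`, `kind`
#'   (`"cohesive"`/`"disjoint"`), `n_nodes`, and a list-column `nodes` of node
#'   indices.
#' @export
classify_switches <- function(traj, rule = c("pair", "dest-only")) {
  .check_traj(traj)
  rule <- .match_rule(rule)
  lab <- traj$labels
  tt <- ncol(lab)
  out <- vector("list", tt - 1L)
  for (t in seq_len(tt - 1L)) {
    src <- lab[, t]
    dst <- lab[, t + 1L]
    moved <- unname(which(src != dst))
    if (length(moved) == 0L) next
    key <- if (rule == "pair") {
      paste(src[moved], dst[moved])
    } else {
      as.character(dst[moved])
    }
    groups <- unname(split(moved, key))
    out[[t]] <- tibble::tibble(
      transition = t,
      source = vapply(groups, function(g) lab[g[1], t], integer(1)),
      destination = vapply(groups, function(g) lab[g[1], t + 1L], integer(1)),
      kind = ifelse(lengths(groups) >= 2L, "cohesive", "disjoint"),
      n_nodes = lengths(groups),
      nodes = groups
    )
  }
  events <- dplyr::bind_rows(out)
  if (nrow(events) == 0L) {
    events <- tibble::tibble(transition = integer(), source = integer(),
                             destination = integer(), kind = character(),
                             n_nodes = integer(), nodes = list())
  }
  events
}

#' Node flexibility
#'
#' Fraction of transitions at which a node changes community label, i.e. the
#' number of switches divided by the `T - 1` opportunities to switch.
#'
#' @inheritParams classify_switches
#' @return a numeric vector of length `N` in `[0, 1]`, named by node.
#' @export
flexibility <- function(traj) {
  .check_traj(traj)
  lab <- traj$labels
  tt <- ncol(lab)
  changes <- rowSums(lab[, -1L, drop = FALSE] != lab[, -tt, drop = FALSE])
  stats::setNames(changes / (tt - 1L), traj$node_ids)
}

#' Node disjointedness
#'
#' How often a node changes community alone: the number of transitions at
#' which the node moves from community i to community j while no other node
#' makes the same i-to-j move, divided by `T - 1`.
#'
#' @inheritParams classify_switches
#' @return a numeric vector of length `N` in `[0, 1]`, named by node.
#' @export
disjointedness <- function(traj, rule = c("pair", "dest-only")) {
  events <- classify_switches(traj, rule)
  d <- numeric(n_nodes(traj))
  lone <- events[events$kind == "disjoint", ]
  for (g in lone$nodes) d[g] <- d[g] + 1L
  stats::setNames(d / (n_layers(traj) - 1L), traj$node_ids)
}

#' Cohesion matrix
#'
#' Pairwise co-switching rates: entry `(n, m)` is the number of transitions at
#' which nodes n and m change community together (same cohesive event),
#' divided by the `T - 1` opportunities. Symmetric with zero diagonal.
#'
#' @inheritParams classify_switches
#' @return an `N x N` matrix of class `cohesion_matrix` with entries in
#'   `[0, 1]`; the denominator `T - 1` is stored in attribute
#'   `"denominator"`.
#' @export
cohesion_matrix <- function(traj, rule = c("pair", "dest-only")) {
  events <- classify_switches(traj, rule)
  n <- n_nodes(traj)
  cm <- matrix(0, n, n, dimnames = list(traj$node_ids, traj$node_ids))
  coh <- events[events$kind == "cohesive", ]
  for (g in coh$nodes) cm[g, g] <- cm[g, g] + 1
  diag(cm) <- 0
  cm <- cm / (n_layers(traj) - 1L)
  structure(cm, class = c("cohesion_matrix", "matrix", "array"),
            denominator = n_layers(traj) - 1L)
}

#' Cohesion strength
#'
#' Row sums of the cohesion matrix, ignoring the diagonal: the expected
#' number of partners a node co-switches with per transition, in
#' `[0, N - 1]`.
#'
#' @param x a `community_trajectory` or a precomputed [cohesion_matrix()].
#' @param rule passed to [cohesion_matrix()] when `x` is a trajectory.
#' @return a numeric vector of length `N`, named by node.
#' @export
cohesion_strength <- function(x, rule = c("pair", "dest-only")) {
  cm <- if (inherits(x, "cohesion_matrix")) x else cohesion_matrix(x, rule)
  rowSums(cm)
}

#' Per-node dynamic community metrics of one trajectory
#'
#' Computes flexibility, disjointedness, the per-node cohesive change rate
#' (fraction of transitions spent in a cohesive event; flexibility =
#' disjointedness + cohesion), and cohesion strength.
#'
#' @inheritParams classify_switches
#' @return a tibble with columns `node`, `flexibility`, `disjointedness`,
#'   `cohesion`, `cohesion_strength`.
#' @export
node_metrics <- function(traj, rule = c("pair", "dest-only")) {
  rule <- .match_rule(rule)
  events <- classify_switches(traj, rule)
  n <- n_nodes(traj)
  denom <- n_layers(traj) - 1L
  dis <- numeric(n)
  coh <- numeric(n)
  cm <- matrix(0, n, n)
  for (i in seq_len(nrow(events))) {
    g <- events$nodes[[i]]
    if (events$kind[i] == "disjoint") {
      dis[g] <- dis[g] + 1
    } else {
      coh[g] <- coh[g] + 1
      cm[g, g] <- cm[g, g] + 1
    }
  }
  diag(cm) <- 0
  tibble::tibble(
    node = traj$node_ids,
    flexibility = unname(flexibility(traj)),
    disjointedness = dis / denom,
    cohesion = coh / denom,
    cohesion_strength = rowSums(cm) / denom
  )
}

#' Ensemble-averaged dynamic community metrics
#'
#' Community detection is stochastic, so metrics are averaged across an
#' ensemble of optimizations rather than computed on a single partition:
#' each trajectory is scored with [node_metrics()] and the per-node
#' arithmetic mean over the ensemble is returned.
#'
#' @param trajs a list of `community_trajectory` objects sharing `N` and `T`
#'   (e.g. from [optimize_ensemble()]), or a `community_ensemble`.
#' @inheritParams classify_switches
#' @return a tibble of per-node means with class `comdyn_metrics`; whole-
#'   network means are available via [glance()].
#' @export
ensemble_metrics <- function(trajs, rule = c("pair", "dest-only")) {
  if (inherits(trajs, "community_ensemble")) trajs <- trajs$trajectories
  stopifnot(length(trajs) >= 1)
  dims <- vapply(trajs, function(x) c(n_nodes(x), n_layers(x)), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("trajectories in an ensemble must share N and T", call. = FALSE)
  }
  per_run <- lapply(trajs, node_metrics, rule = rule)
  avg <- per_run[[1]][, -1]
  for (i in seq_along(per_run)[-1]) avg <- avg + per_run[[i]][, -1]
  avg <- avg / length(per_run)
  out <- dplyr::bind_cols(tibble::tibble(node = trajs[[1]]$node_ids), avg)
  class(out) <- c("comdyn_metrics", class(out))
  attr(out, "n_runs") <- length(per_run)
  out
}

#' @export
glance.comdyn_metrics <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x),
    n_runs = attr(x, "n_runs") %||% 1L,
    mean_flexibility = mean(x$flexibility),
    mean_disjointedness = mean(x$disjointedness),
    mean_cohesion = mean(x$cohesion),
    mean_cohesion_strength = mean(x$cohesion_strength)
  )
}
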