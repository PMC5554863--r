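# Multilayer modularity and its Louvain-style greedy maximization.
#
# Quality function (ordinal interlayer coupling, uniform gamma and omega):
#
#   Q = 1/(2 mu) * sum_{ijlr} [ (A_ijl - gamma * P_ijl) delta_lr
#                               + delta_ij * omega * 1(|l - r| = 1) ]
#                  * delta(g_il, g_jr)
#
# with P the per-layer Newman-Girvan null k_i k_j / (2m) and
# 2 mu = sum of all intra-layer weight + 2 * omega * N * (T - 1), the total
# intra-layer plus interlayer coupling weight. The i = j null terms are part
# of the sum, exactly as in static Newman-Girvan modularity.

#' Newman–Girvan null model of one layer
#'
#' Expected edge weight under random mixing that preserves node strength:
#' `P_ij = k_i k_j / (2m)` with `k_i` the strength of node i and `2m` the
#' total weight `sum(A)`. Mass is conserved: `sum(P) == sum(A)`.
#'
#' @param layer a symmetric non-negative `N x N` matrix.
#' @return a list with `P` (`N x N` matrix), `k` (strength vector), and `m`
#'   (half the total weight).
#' @export
ng_null <- function(layer) {
  layer <- as.matrix(layer)
  stopifnot(is.numeric(layer), nrow(layer) == ncol(layer))
  if (max(abs(layer - t(layer))) > 1e-9) {
    stop("layer must be symmetric", call. = FALSE)
  }
  if (min(layer) < 0) stop("layer must be non-negative", call. = FALSE)
  k <- rowSums(layer)
  m2 <- sum(k)
  if (m2 <= 0) stop("all-zero layer: Newman-Girvan null is degenerate",
                    call. = FALSE)
  list(P = tcrossprod(k) / m2, k = k, m = m2 / 2)
}

#' Modularity parameters
#'
#' @param gamma structural resolution (> 0): weight of the intra-layer null
#'   model. Larger values favour more, smaller communities. Default 1.
#' @param omega temporal coupling (>= 0) between a node and itself in
#'   consecutive layers. Larger values favour persistent labels. Default 1.
#' @param n_opt ensemble size: number of independent optimizations.
#' @param seed integer seed controlling all optimizer randomness.
#' @return a list of class `modularity_params`.
#' @export
modularity_params <- function(gamma = 1, omega = 1, n_opt = 100, seed = 1) {
  stopifnot(gamma > 0, omega >= 0, n_opt >= 1)
  structure(list(gamma = gamma, omega = omega, n_opt = as.integer(n_opt),
                 seed = as.integer(seed)),
            class = "modularity_params")
}

# Supra-modularity matrix over the N*T node-layer index (node varies fastest)
# plus the normalization 2*mu. B holds (A - gamma P) in diagonal blocks and
# omega on the diagonals of adjacent off-diagonal blocks.
supra_modularity_matrix <- function(net, gamma = 1, omega = 1) {
  n <- n_nodes(net)
  tt <- n_layers(net)
  nt <- n * tt
  b <- matrix(0, nt, nt)
  intra <- 0
  for (l in seq_len(tt)) {
    a <- net$layers[[l]]
    nulls <- ng_null(a)
    idx <- (l - 1L) * n + seq_len(n)
    b[idx, idx] <- a - gamma * nulls$P
    intra <- intra + sum(a)
  }
  if (tt >= 2 && omega > 0) {
    for (l in seq_len(tt - 1L)) {
      i <- (l - 1L) * n + seq_len(n)
      j <- l * n + seq_len(n)
      b[cbind(i, j)] <- omega
      b[cbind(j, i)] <- omega
    }
  }
  list(B = b, mu2 = intra + 2 * omega * n * (tt - 1L))
}

#' Multilayer modularity of a given trajectory
#'
#' Evaluates the multilayer quality function Q for a community trajectory:
#' intra-layer terms compare each layer with its Newman–Girvan null at
#' resolution `gamma`; interlayer terms reward a node for keeping its label
#' across consecutive layers with weight `omega`. Normalized by `2*mu`, the
#' total intra-layer weight plus total coupling weight. Q is invariant under
#' global relabelling of communities.
#'
#' @param net a [multilayer_network()].
#' @param traj a [community_trajectory()] with matching `N` and `T`.
#' @param gamma,omega resolution and coupling parameters (see
#'   [modularity_params()]).
#' @return a double, with the normalization stored in attribute `"mu2"`.
#' @export
multilayer_q <- function(net, traj, gamma = 1, omega = 1) {
  stopifnot(inherits(net, "multilayer_network"),
            inherits(traj, "community_trajectory"))
  if (n_nodes(net) != n_nodes(traj) || n_layers(net) != n_layers(traj)) {
    stop("network and trajectory dimensions differ", call. = FALSE)
  }
  n <- n_nodes(net)
  tt <- n_layers(net)
  lab <- traj$labels
  qnum <- 0
  intra <- 0
  for (l in seq_len(tt)) {
    a <- net$layers[[l]]
    nulls <- ng_null(a)
    same <- outer(lab[, l], lab[, l], "==")
    qnum <- qnum + sum((a - gamma * nulls$P)[same])
    intra <- intra + sum(a)
  }
  if (tt >= 2) {
    persist <- lab[, -1L, drop = FALSE] == lab[, -tt, drop = FALSE]
    qnum <- qnum + 2 * omega * sum(persist)
  }
  mu2 <- intra + 2 * omega * n * (tt - 1L)
  structure(qnum / mu2, mu2 = mu2)
}

.norm_labels <- function(x) match(x, sort(unique(x)))

# One Louvain level: greedy node sweeps over the (current) weight matrix b,
# starting from communities `comm`, until no single move increases the
# quality numerator by more than tol. Sweep order is re-randomized each pass.
# Ties are broken toward the incumbent community, then the lowest candidate
# label.
louvain_one_level <- function(b, comm = seq_len(nrow(b)), tol = 1e-10) {
  n <- nrow(b)
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      w <- b[i, ]
      w[i] <- 0
      to_comm <- rowsum(w, comm, reorder = FALSE)
      cands <- as.integer(rownames(to_comm))
      cur <- comm[i]
      w_cur <- if (any(comm[-i] == cur)) to_comm[match(cur, cands)] else 0
      # candidate "fresh" singleton community (weight 0) lets a node with a
      # net-negative attachment leave its community
      cands <- c(cands, n + i)
      gain <- c(to_comm, 0) - w_cur
      best <- max(gain)
      if (best > tol) {
        hits <- cands[gain >= best - 1e-12]
        if (cur %in% hits) next
        comm[i] <- min(hits)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  comm
}

#' Louvain-style maximization of multilayer modularity
#'
#' Greedy local optimization over node-layers: every node-layer starts as its
#' own singleton community in one global label space, node-layers are swept
#' in random order and moved to the neighbouring community with the largest
#' modularity gain, then communities are contracted into super-nodes and the
#' process repeats until no move improves Q. The result is a local maximum:
#' no single node-layer reassignment increases Q.
#'
#' @inheritParams multilayer_q
#' @param seed integer seed for the randomized sweep order.
#' @return a list of class `community_detection` with elements `trajectory`
#'   (a `community_trajectory` whose labels are consistent across layers),
#'   `q` (the attained multilayer modularity), `mu2`, and the parameters.
#' @export
louvain_multilayer <- function(net, gamma = 1, omega = 1, seed = 1) {
  stopifnot(inherits(net, "multilayer_network"))
  n <- n_nodes(net)
  tt <- n_layers(net)
  sup <- supra_modularity_matrix(net, gamma, omega)
  membership <- with_local_seed(seed, {
    b <- sup$B
    nt <- nrow(b)
    memb <- .norm_labels(louvain_one_level(b))
    # Iterated refinement: alternate sweeps over aggregated communities with
    # sweeps over individual node-layers until neither finds an improving
    # move, so the result is a local maximum at node-layer granularity.
    repeat {
      k <- max(memb)
      if (k > 1L && k < nt) {
        s <- matrix(0, nt, k)
        s[cbind(seq_len(nt), memb)] <- 1
        bagg <- crossprod(s, b %*% s)
        sub <- .norm_labels(louvain_one_level(bagg))
        if (max(sub) < k) {
          memb <- .norm_labels(sub[memb])
          next
        }
      }
      memb2 <- .norm_labels(louvain_one_level(b, memb))
      if (identical(memb2, memb)) break
      memb <- memb2
    }
    memb
  })
  lab <- matrix(membership, nrow = n, ncol = tt)
  traj <- community_trajectory(lab, node_ids = net$node_ids)
  q <- multilayer_q(net, traj, gamma, omega)
  structure(list(trajectory = traj, q = as.numeric(q),
                 mu2 = attr(q, "mu2"), gamma = gamma, omega = omega,
                 seed = as.integer(seed)),
            class = "community_detection")
}

#' @export
print.community_detection <- function(x, ...) {
  cat("<community_detection> Q = ", format(x$q, digits = 6), ", ",
      length(unique(as.vector(x$trajectory$labels))), " communities",
      " (gamma = ", x$gamma, ", omega = ", x$omega, ")\n", sep = "")
  invisible(x)
}

#' @export
glance.community_detection <- function(x, ...) {
  tibble::tibble(
    q = x$q,
    n_communities = length(unique(as.vector(x$trajectory$labels))),
    n_nodes = n_nodes(x$trajectory),
    n_layers = n_layers(x$trajectory),
    gamma = x$gamma,
    omega = x$omega
  )
}

#' @export
tidy.community_detection <- function(x, ...) {
  lab <- x$trajectory$labels
  tibble::tibble(
    node = rep(x$trajectory$node_ids, times = ncol(lab)),
    layer = rep(seq_len(ncol(lab)), each = nrow(lab)),
    community = as.integer(lab)
  )
}

#' Ensemble of independent modularity optimizations
#'
#' Runs [louvain_multilayer()] `n_opt` times with per-run seeds derived
#' deterministically from `seed`. Because the greedy optimizer is stochastic
#' and the modularity landscape is nearly degenerate, dynamic metrics should
#' be averaged over such an ensemble ([ensemble_metrics()]).
#'
#' @inheritParams louvain_multilayer
#' @param n_opt number of optimizations.
#' @return a list of class `community_ensemble` with elements `trajectories`
#'   (list of `community_trajectory`), `q` (numeric vector), and the
#'   parameters.
#' @export
optimize_ensemble <- function(net, gamma = 1, omega = 1, n_opt = 100,
                              seed = 1) {
  seeds <- derive_seeds(seed, n_opt)
  fits <- lapply(seeds, function(s) louvain_multilayer(net, gamma, omega, s))
  structure(list(trajectories = lapply(fits, `[[`, "trajectory"),
                 q = vapply(fits, `[[`, numeric(1), "q"),
                 gamma = gamma, omega = omega, n_opt = as.integer(n_opt),
                 seed = as.integer(seed)),
            class = "community_ensemble")
}

#' @export
print.community_ensemble <- function(x, ...) {
  cat("<community_ensemble> ", x$n_opt, " optimizations, Q in [",
      format(min(x$q), digits = 6), ", ", format(max(x$q), digits = 6),
      "]\n", sep = "")
  invisible(x)
}
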