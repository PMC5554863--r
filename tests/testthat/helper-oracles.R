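# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with explicit loops straight from the definitions,
# sharing no code with the package internals.

# Per-node dynamic metrics by direct scanning of each transition.
oracle_metrics <- function(lab, rule = c("pair", "dest-only")) {
  rule <- match.arg(rule)
  n <- nrow(lab)
  tt <- ncol(lab)
  flex <- dis <- coh <- numeric(n)
  cmat <- matrix(0, n, n)
  for (t in seq_len(tt - 1)) {
    movers <- which(lab[, t] != lab[, t + 1])
    for (i in movers) {
      flex[i] <- flex[i] + 1
      same_move <- if (rule == "pair") {
        lab[movers, t] == lab[i, t] & lab[movers, t + 1] == lab[i, t + 1]
      } else {
        lab[movers, t + 1] == lab[i, t + 1]
      }
      partners <- setdiff(movers[same_move], i)
      if (length(partners) == 0) {
        dis[i] <- dis[i] + 1
      } else {
        coh[i] <- coh[i] + 1
        cmat[i, partners] <- cmat[i, partners] + 1
      }
    }
  }
  list(flexibility = flex / (tt - 1), disjointedness = dis / (tt - 1),
       cohesion = coh / (tt - 1), cohesion_matrix = cmat / (tt - 1),
       cohesion_strength = rowSums(cmat) / (tt - 1))
}

# Multilayer modularity by quadruple loop over the printed formula.
oracle_q <- function(net, lab, gamma, omega) {
  n <- nrow(lab)
  tt <- ncol(lab)
  nulls <- lapply(net$layers, function(a) {
    k <- rowSums(a)
    outer(k, k) / sum(k)
  })
  num <- 0
  intra <- 0
  for (l in seq_len(tt)) intra <- intra + sum(net$layers[[l]])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (l in seq_len(tt)) for (r in seq_len(tt)) {
      if (lab[i, l] == lab[j, r]) {
        if (l == r) num <- num + net$layers[[l]][i, j] - gamma * nulls[[l]][i, j]
        if (i == j && abs(l - r) == 1) num <- num + omega
      }
    }
  }
  num / (intra + 2 * omega * n * (tt - 1))
}

# All set partitions of n items as restricted growth strings.
all_partitions <- function(n) {
  res <- list()
  s <- integer(n)
  s[1] <- 1L
  rec <- function(i, mx) {
    if (i > n) {
      res[[length(res) + 1L]] <<- s
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) {
      s[i] <<- v
      rec(i + 1L, max(mx, v))
    }
  }
  if (n == 1) return(list(1L))
  rec(2L, 1L)
  res
}

# Independent BH step-up: reject all p up to the largest k with
# p(k) <= k q / M.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  kmax <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k * q / m) kmax <- k
  }
  rej <- logical(m)
  if (kmax > 0) rej[ord[seq_len(kmax)]] <- TRUE
  rej
}

# Strip class/names/extra attributes from a matrix, keeping only dim.
bare_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# Random symmetric zero-diagonal stack for fuzzing.
random_stack <- function(n, tt, max_w = 1) {
  layers <- lapply(seq_len(tt), function(t) {
    a <- matrix(stats::runif(n * n, 0, max_w), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    a
  })
  multilayer_network(layers)
}

random_trajectory <- function(n, tt, k) {
  community_trajectory(matrix(sample.int(k, n * tt, replace = TRUE), n, tt))
}

# Per-node metrics recomputed from an event log alone (dual bookkeeping).
metrics_from_log <- function(events, n, tt) {
  flex <- dis <- coh <- numeric(n)
  cmat <- matrix(0, n, n)
  for (i in seq_len(nrow(events))) {
    g <- events$nodes[[i]]
    flex[g] <- flex[g] + 1
    if (events$kind[i] == "disjoint") {
      dis[g] <- dis[g] + 1
    } else {
      coh[g] <- coh[g] + 1
      cmat[g, g] <- cmat[g, g] + 1
    }
  }
  diag(cmat) <- 0
  list(flexibility = flex / (tt - 1), disjointedness = dis / (tt - 1),
       cohesion = coh / (tt - 1),
       cohesion_strength = rowSums(cmat) / (tt - 1))
}
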