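# Synthetic test bed: planted community trajectories with exact ground-truth
# switching events, multilayer networks and band-limited time series that
# realize them, and noisy double-exponential learning curves.

#' Specification of a planted community process
#'
#' Defaults describe a moderately sized, strongly modular temporal network:
#' 3 equal communities of 10 nodes over 10 windows, a cohesive group move of
#' 3 nodes at 15% of transitions, lone (disjoint) moves at 10% per node per
#' transition, and block weights 0.9 (within) / 0.1 (between) with sd 0.05
#' edge noise. `preset = "paper-like"` switches to 112 nodes and 25 windows,
#' the scale of a whole-brain windowed coherence analysis.
#'
#' @param n_nodes,n_layers,k network size and number of initial communities.
#' @param p_cohesive per-transition probability of one cohesive group event.
#' @param group_size nodes per cohesive event (>= 2).
#' @param p_disjoint per-node per-transition probability of a lone switch.
#' @param w_in,w_out mean within-/between-community edge weight in `[0, 1]`.
#' @param edge_noise sd of the truncated-Gaussian weight noise.
#' @param seed integer seed.
#' @param preset `"default"` or `"paper-like"` (N = 112, T = 25).
#' @return a list of class `plant_spec`.
#' @export
plant_spec <- function(n_nodes = 30, n_layers = 10, k = 3,
                       p_cohesive = 0.15, group_size = 3, p_disjoint = 0.1,
                       w_in = 0.9, w_out = 0.1, edge_noise = 0.05, seed = 1,
                       preset = c("default", "paper-like")) {
  preset <- match.arg(preset)
  if (preset == "paper-like") {
    n_nodes <- 112
    n_layers <- 25
  }
  stopifnot(p_cohesive >= 0, p_cohesive <= 1, p_disjoint >= 0,
            p_disjoint <= 1, w_out >= 0, w_out < w_in, w_in <= 1,
            group_size >= 2, k >= 1, k <= n_nodes, n_layers >= 2,
            edge_noise >= 0)
  if (group_size > n_nodes %/% k) {
    stop("infeasible spec: group_size exceeds the smallest initial community",
         call. = FALSE)
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 n_layers = as.integer(n_layers), k = as.integer(k),
                 p_cohesive = p_cohesive, group_size = as.integer(group_size),
                 p_disjoint = p_disjoint, w_in = w_in, w_out = w_out,
                 edge_noise = edge_noise, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Plant a community trajectory with known switching events
#'
#' The first layer is a balanced K-partition. At each transition, with
#' probability `p_cohesive` a uniformly chosen set of `group_size`
#' co-members moves together to a uniformly chosen other community (one
#' cohesive event); every remaining node then moves alone with probability
#' `p_disjoint` to a community that no other node is entering from its source
#' — so each planted lone move is guaranteed to classify as disjoint and the
#' emitted event log is exact ground truth.
#'
#' @param spec a [plant_spec()].
#' @return a list with `trajectory` (a [community_trajectory()]) and `events`
#'   (a tibble in the [classify_switches()] schema).
#' @export
plant_trajectory <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  n <- spec$n_nodes
  tt <- spec$n_layers
  k <- spec$k
  lab <- matrix(0L, n, tt)
  lab[, 1] <- sort(rep_len(seq_len(k), n))
  events <- list()
  with_local_seed(spec$seed, {
    for (t in seq_len(tt - 1L)) {
      cur <- lab[, t]
      nxt <- cur
      used_pairs <- character(0)
      in_event <- logical(n)
      if (k >= 2 && runif(1) < spec$p_cohesive) {
        sizes <- table(cur)
        eligible <- as.integer(names(sizes)[sizes >= spec$group_size])
        if (length(eligible) > 0) {
          src <- if (length(eligible) == 1) eligible else sample(eligible, 1)
          members <- which(cur == src)
          members <- if (length(members) == spec$group_size) members else
            sample(members, spec$group_size)
          dst_opts <- setdiff(seq_len(k), src)
          dst <- if (length(dst_opts) == 1) dst_opts else sample(dst_opts, 1)
          nxt[members] <- dst
          in_event[members] <- TRUE
          used_pairs <- paste(src, dst)
          events[[length(events) + 1L]] <- tibble::tibble(
            transition = t, source = src, destination = dst,
            kind = "cohesive", n_nodes = length(members),
            nodes = list(sort(members)))
        }
      }
      if (k >= 2 && spec$p_disjoint > 0) {
        movers <- which(!in_event & runif(n) < spec$p_disjoint)
        for (i in movers[sample.int(length(movers))]) {
          src <- cur[i]
          cand <- setdiff(seq_len(k), src)
          cand <- cand[!(paste(src, cand) %in% used_pairs)]
          if (length(cand) == 0) next  # no destination keeps the move lone
          dst <- if (length(cand) == 1) cand else sample(cand, 1)
          nxt[i] <- dst
          used_pairs <- c(used_pairs, paste(src, dst))
          events[[length(events) + 1L]] <- tibble::tibble(
            transition = t, source = src, destination = dst,
            kind = "disjoint", n_nodes = 1L, nodes = list(i))
        }
      }
      lab[, t + 1L] <- nxt
    }
  })
  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(transition = integer(), source = integer(),
                   destination = integer(), kind = character(),
                   n_nodes = integer(), nodes = list())
  events <- dplyr::arrange(events, .data$transition, .data$kind,
                           .data$source, .data$destination)
  list(trajectory = community_trajectory(lab), events = events)
}

#' Realize a weighted multilayer network from a trajectory
#'
#' Per layer, edge `(i, j)` is drawn from a Gaussian centred at `w_in` if the
#' two nodes share a community in that layer and `w_out` otherwise, with sd
#' `edge_noise`, clipped to `[0, 1]`; symmetric with zero diagonal.
#'
#' @param traj a [community_trajectory()].
#' @param spec a [plant_spec()] supplying `w_in`, `w_out`, `edge_noise`.
#' @param seed integer seed (default: `spec$seed + 1`).
#' @return a [multilayer_network()].
#' @export
realize_network <- function(traj, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(traj, "community_trajectory"),
            inherits(spec, "plant_spec"))
  n <- n_nodes(traj)
  layers <- with_local_seed(seed, {
    lapply(seq_len(n_layers(traj)), function(t) {
      g <- traj$labels[, t]
      same <- outer(g, g, "==")
      mu <- ifelse(same, spec$w_in, spec$w_out)
      a <- matrix(0, n, n)
      ut <- upper.tri(a)
      a[ut] <- pmin(pmax(mu[ut] + rnorm(sum(ut), 0, spec$edge_noise), 0), 1)
      a + t(a)
    })
  })
  multilayer_network(layers, node_ids = traj$node_ids, mode = "coherence")
}

# Zero-mean unit-variance band-limited Gaussian signal of length m.
.bandlimited_noise <- function(m, dt, f_low, f_high) {
  freqs <- seq(0, m - 1) / (m * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= f_low & freqs <= f_high
  z <- stats::fft(rnorm(m))
  z[!keep] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / m
  as.vector(scale(x))
}

#' Realize band-limited time series from a trajectory
#'
#' Within each layer span, every community shares one latent band-limited
#' Gaussian signal; a node's series is its community's latent plus white
#' noise at the stated signal-to-noise (variance) ratio. Spans are
#' concatenated, so community structure in the `[f_low, f_high]` band follows
#' the planted trajectory layer by layer.
#'
#' @param traj a [community_trajectory()].
#' @param samples_per_layer samples per window span (>= 16).
#' @param f_low,f_high band edges in Hz.
#' @param snr signal-to-noise variance ratio; `Inf` for noise-free.
#' @param sampling_interval seconds per sample.
#' @param seed integer seed.
#' @return a [timeseries_set()] of `N x (T * samples_per_layer)` samples.
#' @export
realize_timeseries <- function(traj, samples_per_layer = 80, f_low = 0.06,
                               f_high = 0.12, snr = 1,
                               sampling_interval = 2, seed = 1) {
  stopifnot(inherits(traj, "community_trajectory"), samples_per_layer >= 16,
            snr > 0)
  n <- n_nodes(traj)
  tt <- n_layers(traj)
  m <- samples_per_layer
  vals <- with_local_seed(seed, {
    blocks <- lapply(seq_len(tt), function(t) {
      g <- traj$labels[, t]
      latents <- lapply(unique(g), function(c)
        .bandlimited_noise(m, sampling_interval, f_low, f_high))
      names(latents) <- as.character(unique(g))
      block <- t(vapply(seq_len(n), function(i) latents[[as.character(g[i])]],
                        numeric(m)))
      if (is.finite(snr)) {
        block <- block + matrix(rnorm(n * m, 0, 1 / sqrt(snr)), n, m)
      }
      block
    })
    do.call(cbind, blocks)
  })
  timeseries_set(vals, sampling_interval, node_ids = traj$node_ids)
}

#' Generate a noisy double-exponential learning curve
#'
#' `MT_t = (D1 exp(-t kappa) + D2 exp(-t lambda)) * (1 + e_t)` with Gaussian
#' multiplicative noise `e_t ~ N(0, noise_sd)`; a fraction `outlier_frac` of
#' trials is additionally multiplied by 3 (aberrant trials). Movement times
#' are clipped to stay positive.
#'
#' @param d1,kappa,d2,lambda model parameters (`d1, d2 >= 0`,
#'   `kappa >= lambda >= 0`).
#' @param noise_sd sd of the multiplicative noise.
#' @param outlier_frac fraction of trials turned into 3x outliers.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return a tibble with columns `trial`, `mt` (seconds).
#' @export
generate_learning_curve <- function(d1 = 2, kappa = 0.1, d2 = 1,
                                    lambda = 0.01, noise_sd = 0.05,
                                    outlier_frac = 0, n_trials = 100,
                                    seed = 1) {
  stopifnot(d1 >= 0, d2 >= 0, kappa >= lambda, lambda >= 0, noise_sd >= 0,
            outlier_frac >= 0, outlier_frac < 1, n_trials >= 1)
  t <- seq_len(n_trials)
  base <- .dexp_model(t, d1, kappa, d2, lambda)
  mt <- with_local_seed(seed, {
    out <- base * (1 + rnorm(n_trials, 0, noise_sd))
    n_out <- floor(outlier_frac * n_trials)
    if (n_out > 0) {
      idx <- sample.int(n_trials, n_out)
      out[idx] <- out[idx] * 3
    }
    out
  })
  tibble::tibble(trial = t, mt = pmax(mt, .Machine$double.eps))
}
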