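# Temporal null model: the same layers in uniformly random order. Each layer
# matrix is preserved bit-identically (intralayer connections untouched) and
# interlayer coupling stays ordinal between consecutive positions of the
# permuted order, so only the temporal ordering of windows is destroyed.

#' Temporally permute a multilayer network
#'
#' Reorders the layers of `net` uniformly at random (or by an explicit
#' permutation), preserving every layer matrix exactly.
#'
#' @param net a [multilayer_network()].
#' @param seed integer seed; ignored when `perm` is given.
#' @param perm optional explicit permutation of `1:T`.
#' @return a `multilayer_network` with attribute `"perm"` recording the
#'   ordering used (`out$layers[[t]] == net$layers[[perm[t]]]`).
#' @export
temporal_permute <- function(net, seed = 1, perm = NULL) {
  stopifnot(inherits(net, "multilayer_network"))
  tt <- n_layers(net)
  if (tt < 2) stop("need T >= 2 layers to permute", call. = FALSE)
  if (is.null(perm)) {
    perm <- with_local_seed(seed, sample.int(tt))
  }
  stopifnot(length(perm) == tt, sort(perm) == seq_len(tt))
  out <- multilayer_network(net$layers[perm], node_ids = net$node_ids,
                            mode = net$mode)
  attr(out, "perm") <- as.integer(perm)
  out
}

#' Null distribution of a whole-network dynamic metric
#'
#' Generates `n_null` temporally permuted copies of `net`; for each copy,
#' runs an ensemble of `n_opt` modularity optimizations and records the
#' whole-network ensemble-averaged metric. The resulting vector is the
#' reference distribution against which the observed metric of the intact
#' network is tested.
#'
#' @param net a [multilayer_network()].
#' @param metric one of `"cohesion_strength"`, `"disjointedness"`,
#'   `"flexibility"`, `"cohesion"`.
#' @param gamma,omega modularity parameters.
#' @param n_null number of permuted networks.
#' @param n_opt optimizations per permuted network.
#' @param seed master seed; permutations and optimizer seeds derive from it.
#' @param rule cohesion grouping rule, see [classify_switches()].
#' @return a tibble with columns `null_id`, `value`.
#' @export
null_distribution <- function(net,
                              metric = c("cohesion_strength",
                                         "disjointedness", "flexibility",
                                         "cohesion"),
                              gamma = 1, omega = 1, n_null = 100,
                              n_opt = 100, seed = 1,
                              rule = c("pair", "dest-only")) {
  metric <- match.arg(metric)
  rule <- match.arg(rule)
  stopifnot(n_null >= 1, n_opt >= 1)
  seeds <- derive_seeds(seed, 2L * n_null)
  vals <- vapply(seq_len(n_null), function(k) {
    permuted <- temporal_permute(net, seed = seeds[2L * k - 1L])
    ens <- optimize_ensemble(permuted, gamma, omega, n_opt,
                             seed = seeds[2L * k])
    m <- ensemble_metrics(ens, rule = rule)
    mean(m[[metric]])
  }, numeric(1))
  tibble::tibble(null_id = seq_len(n_null), value = vals)
}
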