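#' Multilayer network container
#'
#' An ordered stack of `T` symmetric, non-negative, zero-diagonal `N x N`
#' weighted adjacency matrices sharing one node set. Layer order is temporal
#' order: layer `t` is the network observed in time window `t`.
#'
#' @param layers a list of `N x N` numeric matrices, or a 3-d array with
#'   dimensions `N x N x T`.
#' @param node_ids character vector of `N` unique node labels. Defaults to
#'   `"n1" ... "nN"`.
#' @param mode `"weight"` for general non-negative weights, `"coherence"` for
#'   layers additionally bounded above by 1 (magnitude-squared coherence).
#' @param tol maximum tolerated asymmetry `max |A - t(A)|`; smaller
#'   asymmetries are removed by averaging, larger ones are an error.
#'
#' @return an object of class `multilayer_network`: a list with elements
#'   `layers` (list of matrices), `node_ids`, and `mode`.
#' @export
multilayer_network <- function(layers, node_ids = NULL,
                               mode = c("weight", "coherence"),
                               tol = 1e-9) {
  mode <- match.arg(mode)
  if (is.array(layers) && length(dim(layers)) == 3) {
    layers <- lapply(seq_len(dim(layers)[3]), function(t) layers[, , t])
  }
  if (!is.list(layers) || length(layers) < 1) {
    stop("`layers` must be a non-empty list of matrices", call. = FALSE)
  }
  n <- nrow(layers[[1]])
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  if (anyDuplicated(node_ids) || length(node_ids) != n) {
    stop("`node_ids` must be ", n, " unique labels", call. = FALSE)
  }
  layers <- lapply(seq_along(layers), function(t) {
    a <- as.matrix(layers[[t]])
    if (!is.numeric(a) || nrow(a) != n || ncol(a) != n) {
      stop("layer ", t, " is not a numeric ", n, "x", n, " matrix",
           call. = FALSE)
    }
    if (any(!is.finite(a))) {
      stop("layer ", t, " contains non-finite values", call. = FALSE)
    }
    asym <- max(abs(a - t(a)))
    if (asym > tol) {
      stop("layer ", t, " asymmetric beyond tolerance (max |A - A'| = ",
           signif(asym, 3), ")", call. = FALSE)
    }
    a <- (a + t(a)) / 2
    if (max(abs(diag(a))) > tol) {
      stop("layer ", t, " has a non-zero diagonal; self-edges are not allowed",
           call. = FALSE)
    }
    diag(a) <- 0
    if (min(a) < -tol) {
      stop("layer ", t, " has negative weights", call. = FALSE)
    }
    a[a < 0] <- 0
    if (mode == "coherence" && max(a) > 1 + tol) {
      stop("layer ", t, ": value out of [0,1] under coherence mode",
           call. = FALSE)
    }
    dimnames(a) <- list(node_ids, node_ids)
    a
  })
  structure(list(layers = layers, node_ids = node_ids, mode = mode),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("<multilayer_network> ", n_nodes(x), " nodes x ", n_layers(x),
      " layers (mode: ", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Number of nodes / layers of a multilayer network or trajectory
#' @param x a `multilayer_network` or `community_trajectory`.
#' @return an integer.
#' @export
n_nodes <- function(x) UseMethod("n_nodes")
#' @export
n_nodes.multilayer_network <- function(x) nrow(x$layers[[1]])
#' @export
n_nodes.community_trajectory <- function(x) nrow(x$labels)

#' @rdname n_nodes
#' @export
n_layers <- function(x) UseMethod("n_layers")
#' @export
n_layers.multilayer_network <- function(x) length(x$layers)
#' @export
n_layers.community_trajectory <- function(x) ncol(x$labels)

#' Community trajectory container
#'
#' An `N x T` matrix of integer community labels: entry `(n, t)` is the
#' community that node `n` belongs to in layer `t`. Labels live in one global
#' label space per optimization run, so "node n changed community between
#' layers t and t+1" is simply `labels[n, t] != labels[n, t + 1]`.
#'
#' @param labels integer matrix, `N` nodes by `T` layers, labels >= 1.
#' @param node_ids optional character vector of `N` unique node labels.
#' @return an object of class `community_trajectory`.
#' @export
community_trajectory <- function(labels, node_ids = NULL) {
  labels <- as.matrix(labels)
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    stop("community labels must be finite integers", call. = FALSE)
  }
  if (any(labels < 1)) stop("community labels must be >= 1", call. = FALSE)
  storage.mode(labels) <- "integer"
  n <- nrow(labels)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  if (anyDuplicated(node_ids) || length(node_ids) != n) {
    stop("`node_ids` must be ", n, " unique labels", call. = FALSE)
  }
  rownames(labels) <- node_ids
  colnames(labels) <- paste0("t", seq_len(ncol(labels)))
  structure(list(labels = labels, node_ids = node_ids),
            class = "community_trajectory")
}

#' @export
print.community_trajectory <- function(x, ...) {
  cat("<community_trajectory> ", n_nodes(x), " nodes x ", n_layers(x),
      " layers, ", length(unique(as.vector(x$labels))), " distinct labels\n",
      sep = "")
  invisible(x)
}

#' Regional time-series container
#'
#' Holds `N` concurrently sampled signals (rows) of `S` samples (columns) with
#' a fixed sampling interval, e.g. region-averaged BOLD series.
#'
#' @param values `N x S` numeric matrix, one row per node/region.
#' @param sampling_interval seconds per sample (e.g. the scanner TR).
#' @param node_ids optional `N` unique labels.
#' @return an object of class `timeseries_set`.
#' @export
timeseries_set <- function(values, sampling_interval, node_ids = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("time series contain non-finite values", call. = FALSE)
  }
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1 ||
      sampling_interval <= 0) {
    stop("`sampling_interval` must be a positive scalar (seconds)",
         call. = FALSE)
  }
  n <- nrow(values)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  if (anyDuplicated(node_ids) || length(node_ids) != n) {
    stop("`node_ids` must be ", n, " unique labels", call. = FALSE)
  }
  rownames(values) <- node_ids
  structure(list(values = values, sampling_interval = sampling_interval,
                 node_ids = node_ids),
            class = "timeseries_set")
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat("<timeseries_set> ", nrow(x$values), " nodes x ", ncol(x$values),
      " samples @ ", x$sampling_interval, " s\n", sep = "")
  invisible(x)
}
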