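# Canonical interchange is TAB-delimited text: one matrix per file, or a
# single "stacked" file with blank lines between layers. Node ids and the
# sampling interval travel in a JSON sidecar (<path>.json). Layer indices are
# 1-based in files and reports, consistent with R indexing.

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
}

.format_matrix <- function(m) {
  apply(m, 1, function(row) paste(format(row, digits = 17, trim = TRUE,
                                         scientific = TRUE),
                                  collapse = "\t"))
}

.parse_matrix_lines <- function(lines, what = "numeric", context = "matrix") {
  rows <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(rows)
  if (length(unique(width)) != 1) {
    stop("ragged rows in ", context, call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (any(is.na(vals))) {
    stop("non-numeric entry in ", context, call. = FALSE)
  }
  m <- matrix(vals, nrow = length(rows), byrow = TRUE)
  if (what == "integer") {
    if (any(m != round(m))) stop("non-integer labels in ", context,
                                 call. = FALSE)
    storage.mode(m) <- "integer"
  }
  m
}

#' Read / write a multilayer network as delimited text
#'
#' `read_multilayer()` accepts either a character vector of per-layer TSV
#' files (layer order = file order) or a single stacked file in which layers
#' are separated by blank lines. `write_multilayer()` writes the stacked
#' format plus a JSON sidecar carrying node ids and the mode.
#'
#' @param paths one or more file paths.
#' @param mode,node_ids see [multilayer_network()]; `node_ids` read from the
#'   sidecar when present.
#' @return a `multilayer_network`.
#' @export
read_multilayer <- function(paths, mode = c("weight", "coherence"),
                            node_ids = NULL) {
  mode <- match.arg(mode)
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  if (length(paths) == 1) {
    lines <- readLines(paths)
    blank <- grepl("^\\s*$", lines)
    grp <- cumsum(c(TRUE, diff(blank) == -1))[!blank]
    chunks <- split(lines[!blank], grp)
    mats <- lapply(seq_along(chunks), function(i) {
      .parse_matrix_lines(chunks[[i]], context = paste0("layer ", i, " of ",
                                                        paths))
    })
    meta <- .read_sidecar(paths)
  } else {
    mats <- lapply(paths, function(p) {
      lines <- readLines(p)
      .parse_matrix_lines(lines[!grepl("^\\s*$", lines)], context = p)
    })
    meta <- .read_sidecar(paths[[1]])
  }
  shapes <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    stop("shape mismatch between layers: ", paste(unique(shapes),
                                                  collapse = ", "),
         call. = FALSE)
  }
  if (is.null(node_ids) && !is.null(meta$node_ids)) node_ids <- meta$node_ids
  if (is.null(mode) && !is.null(meta$mode)) mode <- meta$mode
  multilayer_network(mats, node_ids = node_ids, mode = mode)
}

#' @rdname read_multilayer
#' @param net a `multilayer_network`.
#' @param path output path for the stacked file.
#' @export
write_multilayer <- function(net, path) {
  stopifnot(inherits(net, "multilayer_network"))
  blocks <- lapply(net$layers, .format_matrix)
  out <- unlist(lapply(seq_along(blocks), function(i) {
    if (i < length(blocks)) c(blocks[[i]], "") else blocks[[i]]
  }))
  writeLines(out, path)
  .write_sidecar(path, list(node_ids = net$node_ids, mode = net$mode,
                            n_layers = n_layers(net)))
  invisible(path)
}

#' Read / write a community trajectory (N x T integer labels) as TSV
#'
#' @param path file path.
#' @param node_ids optional node labels; read from the sidecar when present.
#' @return `read_trajectory()` returns a `community_trajectory`.
#' @export
read_trajectory <- function(path, node_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  m <- .parse_matrix_lines(lines[!grepl("^\\s*$", lines)], what = "integer",
                           context = path)
  meta <- .read_sidecar(path)
  if (is.null(node_ids) && !is.null(meta$node_ids)) node_ids <- meta$node_ids
  community_trajectory(m, node_ids = node_ids)
}

#' @rdname read_trajectory
#' @param traj a `community_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "community_trajectory"))
  writeLines(apply(traj$labels, 1, paste, collapse = "\t"), path)
  .write_sidecar(path, list(node_ids = traj$node_ids))
  invisible(path)
}

#' Read / write a regional time-series set (N x S) as TSV
#'
#' The sampling interval (seconds) is stored in the JSON sidecar; when absent
#' on read it must be supplied.
#'
#' @param path file path.
#' @param sampling_interval seconds per sample; overrides the sidecar.
#' @param node_ids optional node labels.
#' @return `read_timeseries()` returns a `timeseries_set`.
#' @export
read_timeseries <- function(path, sampling_interval = NULL, node_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  m <- .parse_matrix_lines(lines[!grepl("^\\s*$", lines)], context = path)
  meta <- .read_sidecar(path)
  if (is.null(sampling_interval)) sampling_interval <- meta$sampling_interval
  if (is.null(sampling_interval)) {
    stop("`sampling_interval` not given and no sidecar found for ", path,
         call. = FALSE)
  }
  if (is.null(node_ids) && !is.null(meta$node_ids)) node_ids <- meta$node_ids
  timeseries_set(m, sampling_interval, node_ids = node_ids)
}

#' @rdname read_timeseries
#' @param ts a `timeseries_set`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries_set"))
  writeLines(.format_matrix(ts$values), path)
  .write_sidecar(path, list(node_ids = ts$node_ids,
                            sampling_interval = ts$sampling_interval))
  invisible(path)
}

#' Write a per-node metric table to TSV
#'
#' @param metrics a tibble as returned by [node_metrics()] or
#'   [ensemble_metrics()].
#' @param path output path.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_tsv(metrics, path)
  invisible(path)
}
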