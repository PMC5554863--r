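# Classical tests used downstream of the dynamic metrics, plus a permutation
# test and Benjamini-Hochberg FDR control over the (gamma, omega) resolution
# grid. Closed-form tests wrap stats::; the permutation machinery and the
# step-up mask are implemented here.

#' Two-sample and paired t-tests, returned tidily
#'
#' `two_sample_ttest()` is the classical pooled-variance (equal-variance)
#' two-sample t-test with `df = n1 + n2 - 2`; `paired_ttest()` is the paired
#' t-test on elementwise differences.
#'
#' @param x,y numeric vectors (equal length for the paired test).
#' @return a one-row tibble with `statistic`, `df`, `p.value`,
#'   `estimate` (mean difference), and `method`.
#' @export
two_sample_ttest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2, is.finite(x), is.finite(y))
  ht <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value, estimate = mean(x) - mean(y),
                 method = "two-sample t (pooled variance)")
}

#' @rdname two_sample_ttest
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, is.finite(x),
            is.finite(y))
  d <- x - y
  if (stats::sd(d) == 0) {
    # all differences identical; t is 0/0 when the common difference is 0
    if (all(d == 0)) {
      return(tibble::tibble(statistic = 0, df = length(d) - 1, p.value = 1,
                            estimate = 0, method = "paired t"))
    }
    stop("zero variance of paired differences", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value, estimate = mean(d),
                 method = "paired t")
}

#' One-way repeated-measures ANOVA
#'
#' Tests a within-subject condition effect (e.g. scan day) on a metric, with
#' subject as the repeated measure: `F = MS_condition / MS_error` where the
#' error term is the subject-by-condition interaction mean square. Requires a
#' complete balanced table (every subject measured in every condition).
#'
#' @param data a data frame.
#' @param value,subject,condition column names (strings) of the measurement,
#'   the subject identifier, and the within-subject condition.
#' @return a one-row tibble with `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
rm_anova_oneway <- function(data, value = "value", subject = "subject",
                            condition = "condition") {
  y <- data[[value]]
  s <- factor(data[[subject]])
  g <- factor(data[[condition]])
  if (any(table(s, g) != 1)) {
    stop("repeated-measures ANOVA needs a complete balanced table ",
         "(one observation per subject x condition)", call. = FALSE)
  }
  ns <- nlevels(s)
  ng <- nlevels(g)
  grand <- mean(y)
  ss_cond <- ns * sum((tapply(y, g, mean) - grand)^2)
  ss_subj <- ng * sum((tapply(y, s, mean) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- ng - 1
  df2 <- (ns - 1) * (ng - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  if (ms_err <= 0) stop("zero error variance in repeated-measures ANOVA",
                        call. = FALSE)
  f <- ms_cond / ms_err
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Pearson correlation with test
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return a one-row tibble with `estimate` (r), `r.squared`, `statistic`,
#'   `df`, `p.value`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ht$estimate),
                 r.squared = unname(ht$estimate)^2,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value)
}

#' Permutation test on a difference of means
#'
#' Two-sided permutation p-value for the difference-of-means statistic:
#' group labels are shuffled for the unpaired test, difference signs are
#' flipped for the paired test. The p-value uses the add-one convention
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)`, which is valid (never
#' anti-conservative) at any `n_perm`.
#'
#' @param x,y numeric vectors (equal length if `paired`).
#' @param n_perm number of random permutations.
#' @param paired sign-flipping test on `x - y` instead of label shuffling.
#' @param seed integer seed.
#' @return a one-row tibble with `statistic` (observed mean difference),
#'   `p.value`, `n_perm`.
#' @export
permutation_test <- function(x, y, n_perm = 10000, paired = FALSE, seed = 1) {
  stopifnot(n_perm >= 1)
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    obs <- mean(d)
    if (all(d == 0)) {
      return(tibble::tibble(statistic = 0, p.value = 1,
                            n_perm = as.integer(n_perm)))
    }
    perm <- with_local_seed(seed, {
      signs <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                      nrow = length(d))
      colMeans(signs * d)
    })
  } else {
    pooled <- c(x, y)
    if (length(unique(pooled)) == 1L) {
      return(tibble::tibble(statistic = 0, p.value = 1,
                            n_perm = as.integer(n_perm)))
    }
    nx <- length(x)
    obs <- mean(x) - mean(y)
    tot <- sum(pooled)
    nn <- length(pooled)
    perm <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        sx <- sum(pooled[sample.int(nn, nx)])
        sx / nx - (tot - sx) / (nn - nx)
      }, numeric(1))
    })
  }
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
  tibble::tibble(statistic = obs, p.value = p, n_perm = as.integer(n_perm))
}

#' Benjamini–Hochberg false-discovery-rate control
#'
#' Standard step-up procedure: with ordered p-values `p(1) <= ... <= p(M)`,
#' reject all hypotheses up to the largest `k` with `p(k) <= k q / M`. Also
#' returns BH-adjusted p-values (`stats::p.adjust(..., "BH")`), for which
#' `adjusted <= q` is equivalent to rejection.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return a tibble in the input order with `p.value`, `p.adjusted`,
#'   `rejected`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(tibble::tibble(p.value = numeric(), p.adjusted = numeric(),
                          rejected = logical()))
  }
  stopifnot(all(pvals >= 0 & pvals <= 1), q > 0)
  m <- length(pvals)
  ord <- order(pvals)
  thresh <- seq_len(m) * q / m
  ok <- which(pvals[ord] <= thresh)
  kmax <- if (length(ok)) max(ok) else 0L
  rejected <- logical(m)
  if (kmax > 0) rejected[ord[seq_len(kmax)]] <- TRUE
  tibble::tibble(p.value = pvals,
                 p.adjusted = stats::p.adjust(pvals, method = "BH"),
                 rejected = rejected)
}

#' Per-node condition contrast over a (gamma, omega) resolution grid
#'
#' For every node and every grid cell, runs a permutation test between the
#' two conditions' metric values, then controls the FDR with
#' Benjamini–Hochberg. A node is flagged `consistent` when it is rejected in
#' at least `consistency_frac` of the grid cells (default: all of them),
#' which operationalizes "significant consistently over the parameter range".
#'
#' @param data a data frame with columns `node`, `gamma`, `omega`,
#'   `condition` (exactly two levels), `value`, and — for the paired test —
#'   `subject`.
#' @param n_perm permutations per test.
#' @param q FDR level.
#' @param paired use the paired (sign-flip) permutation test, matching
#'   subjects across conditions within each node and grid cell.
#' @param seed integer seed.
#' @param consistency_frac fraction of grid cells in which a node must be
#'   rejected to count as consistent.
#' @param fdr_scope `"cell"` corrects across nodes within each grid cell;
#'   `"pooled"` corrects across the whole node-by-grid table at once.
#' @return a tibble (`node`, `gamma`, `omega`, `statistic`, `p.value`,
#'   `p.adjusted`, `rejected`) of class `grid_contrast`; per-node consistency
#'   is available via [consistent_nodes()].
#' @export
grid_contrast <- function(data, n_perm = 10000, q = 0.05, paired = FALSE,
                          seed = 1, consistency_frac = 1,
                          fdr_scope = c("cell", "pooled")) {
  fdr_scope <- match.arg(fdr_scope)
  needed <- c("node", "gamma", "omega", "condition", "value")
  if (paired) needed <- c(needed, "subject")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("`data` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  conds <- sort(unique(as.character(data$condition)))
  if (length(conds) != 2) stop("`condition` must have exactly two levels",
                               call. = FALSE)
  cells <- dplyr::distinct(data, .data$gamma, .data$omega)
  full <- tidyr::expand_grid(node = unique(data$node),
                             gamma = cells$gamma, omega = cells$omega)
  have <- dplyr::distinct(data, .data$node, .data$gamma, .data$omega)
  if (nrow(dplyr::anti_join(full, have,
                            by = c("node", "gamma", "omega"))) > 0) {
    stop("missing grid cells: every node needs values at every ",
         "(gamma, omega)", call. = FALSE)
  }
  groups <- dplyr::group_split(dplyr::group_by(data, .data$node, .data$gamma,
                                               .data$omega))
  seeds <- derive_seeds(seed, length(groups))
  res <- purrr::map2_dfr(groups, seeds, function(g, s) {
    if (paired) {
      g <- dplyr::arrange(g, .data$condition, .data$subject)
      x <- g$value[g$condition == conds[1]]
      y <- g$value[g$condition == conds[2]]
    } else {
      x <- g$value[g$condition == conds[1]]
      y <- g$value[g$condition == conds[2]]
    }
    pt <- permutation_test(x, y, n_perm = n_perm, paired = paired, seed = s)
    tibble::tibble(node = g$node[1], gamma = g$gamma[1], omega = g$omega[1],
                   statistic = pt$statistic, p.value = pt$p.value)
  })
  if (fdr_scope == "cell") {
    res <- dplyr::group_by(res, .data$gamma, .data$omega)
    res <- dplyr::mutate(res, bh_fdr(.data$p.value, q)[, -1])
    res <- dplyr::ungroup(res)
  } else {
    res <- dplyr::bind_cols(res, bh_fdr(res$p.value, q)[, -1])
  }
  res <- structure(res, class = c("grid_contrast", class(res)),
                   q = q, consistency_frac = consistency_frac)
  res
}

#' Nodes significant consistently across the resolution grid
#'
#' @param contrast a [grid_contrast()] result.
#' @param consistency_frac override the fraction stored in the contrast.
#' @return a tibble with `node`, `frac_rejected`, `consistent`, and
#'   `direction` (sign of the mean statistic across cells).
#' @export
consistent_nodes <- function(contrast, consistency_frac = NULL) {
  stopifnot(inherits(contrast, "grid_contrast"))
  frac <- consistency_frac %||% attr(contrast, "consistency_frac") %||% 1
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(contrast), .data$node),
    frac_rejected = mean(.data$rejected),
    direction = sign(mean(.data$statistic)),
    .groups = "drop"
  )
  out$consistent <- out$frac_rejected >= frac
  out[, c("node", "frac_rejected", "consistent", "direction")]
}
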