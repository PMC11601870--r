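# Fuzzy c-means clustering of standardized group-mean time courses, and
# 5-point logFC trajectory correlations between sexes and tissue pairs.

#' Build the trajectory matrix of z-scored group means
#'
#' Averages normalized values within each (sex, group) cell and z-scores
#' each lipid's row of cell means (mean 0, sd 1) — the clustering input.
#'
#' @param values Lipids x samples matrix of normalized data.
#' @param meta data.frame aligned with columns, with `sex` and `group`.
#' @param groups Group levels in temporal order.
#' @return Lipids x (sex.group) matrix; rows with zero variance across cells
#'   are dropped (recorded in attribute `"dropped"`).
#' @export
trajectory_matrix <- function(values, meta, groups = training_groups()) {
  cell <- paste(meta$sex, meta$group, sep = ".")
  lev <- as.vector(outer(groups, unique(meta$sex),
                         function(g, s) paste(s, g, sep = ".")))
  lev <- lev[lev %in% cell]
  gm <- vapply(lev, function(cl)
    rowMeans(values[, cell == cl, drop = FALSE], na.rm = TRUE),
    numeric(nrow(values)))
  mu <- rowMeans(gm)
  sd_r <- apply(gm, 1L, stats::sd)
  keep <- is.finite(sd_r) & sd_r > 0 & rowSums(!is.finite(gm)) == 0
  z <- (gm[keep, , drop = FALSE] - mu[keep]) / sd_r[keep]
  attr(z, "dropped") <- rownames(values)[!keep]
  z
}

.kmeanspp_init <- function(x, c) {
  n <- nrow(x)
  centers <- matrix(NA_real_, c, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(c - 1L) + 1L) {
    probs <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

.fcm_memberships <- function(d2, m) {
  # u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1)); points on a centroid get
  # membership 1 there (limit convention)
  expo <- 1 / (m - 1)
  zero <- d2 < .Machine$double.eps
  u <- (1 / d2)^expo
  u <- u / rowSums(u)
  hit <- rowSums(zero) > 0L
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Fuzzy c-means clustering
#'
#' Standard alternating optimization of the fuzzy c-means objective
#' `J = sum_ik u_ik^m d_ik^2` (Euclidean distance): membership update
#' `u_ik = 1 / sum_j (d_ik/d_jk)^(2/(m-1))`, centroid update
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`. The objective is nonincreasing
#' every iteration; convergence is declared when the largest centroid shift
#' drops below `tol`. Centroids are seeded with k-means++-style sampling and
#' the best of `n_restarts` runs (lowest objective) is kept.
#'
#' @param x Data matrix (rows clustered), e.g. a [trajectory_matrix()].
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier (> 1; default 1.5).
#' @param seed Integer seed for the restarts.
#' @param tol Centroid-shift convergence tolerance.
#' @param max_iter Maximum iterations per restart.
#' @param n_restarts Random restarts (default 10).
#' @return A `cluster_result`: list with `centroids` (c x variables),
#'   `membership` (rows x c, rows sum to 1), `core` (membership >= 0.5),
#'   `cluster` (hard assignment), `objective` (trace of the best run),
#'   `c`, `m`.
#' @export
cmeans_fuzzy <- function(x, c, m = 1.5, seed = 1L, tol = 1e-8,
                         max_iter = 200L, n_restarts = 10L) {
  stopifnot(is.matrix(x), c >= 2L, c < nrow(x), m > 1)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- .kmeanspp_init(x, c)
    trace <- numeric()
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
      d2[d2 < 0] <- 0
      u <- .fcm_memberships(d2, m)
      um <- u^m
      trace <- c(trace, sum(um * d2))
      new_centers <- (t(um) %*% x) / colSums(um)
      shift <- sqrt(max(rowSums((new_centers - centers)^2)))
      centers <- new_centers
      if (shift < tol) break
    }
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
    d2[d2 < 0] <- 0
    u <- .fcm_memberships(d2, m)
    obj <- sum(u^m * d2)
    if (is.null(best) || obj < best$objective_final) {
      rownames(centers) <- paste0("cluster", seq_len(c))
      dimnames(u) <- list(rownames(x), rownames(centers))
      best <- list(centroids = centers, membership = u, core = u >= 0.5,
                   cluster = max.col(u), objective = trace,
                   objective_final = obj, c = c, m = m)
    }
  }
  structure(best, class = "cluster_result")
}

#' Choose the cluster number by the minimum-centroid-distance elbow
#'
#' Runs the clustering over `c_range`, records the minimum pairwise centroid
#' distance per c (which collapses once c exceeds the number of distinct
#' temporal archetypes), and returns the elbow: the c maximizing the forward
#' second difference of the curve. A flat curve (relative drop < 20%) is
#' flagged low-confidence. The caller may always override — the choice is a
#' diagnostic, not a hard rule.
#'
#' @param x Data matrix.
#' @param c_range Candidate cluster numbers (subset of `[2, nrow(x) - 1]`).
#' @inheritParams cmeans_fuzzy
#' @return List with `c` (elbow choice), `curve` (data.frame c,
#'   min_centroid_dist), `low_confidence`.
#' @export
choose_c <- function(x, c_range = 2:12, m = 1.5, seed = 1L, n_restarts = 5L) {
  c_range <- sort(unique(c_range))
  stopifnot(all(c_range >= 2L), all(c_range <= nrow(x) - 1L))
  md <- vapply(c_range, function(cc) {
    fit <- cmeans_fuzzy(x, cc, m = m, seed = seed, n_restarts = n_restarts)
    min(stats::dist(fit$centroids))
  }, 0)
  curve <- data.frame(c = c_range, min_centroid_dist = md)
  if (length(c_range) < 3L)
    return(list(c = as.integer(c_range[1]), curve = curve,
                low_confidence = TRUE))
  # forward second difference f(c) - 2 f(c+1) + f(c+2), assigned to c
  d2 <- md[seq_len(length(md) - 2L)] - 2 * md[seq_len(length(md) - 2L) + 1L] +
    md[seq_len(length(md) - 2L) + 2L]
  elbow <- as.integer(c_range[which.max(d2)])
  rel_drop <- (max(md) - min(md)) / max(md)
  list(c = elbow, curve = curve, low_confidence = rel_drop < 0.2)
}

#' Five-point logFC trajectory
#'
#' Orders a lipid's timewise logFC estimates and prepends the 0 baseline.
#'
#' @param logfc Named numeric vector of logFC at the training timepoints.
#' @param timepoints Timepoint order (default 1w, 2w, 4w, 8w).
#' @return Numeric vector of length `length(timepoints) + 1`, starting at 0.
#' @export
logfc_trajectory <- function(logfc, timepoints = c("1w", "2w", "4w", "8w")) {
  stopifnot(all(timepoints %in% names(logfc)))
  c(0, unname(logfc[timepoints]))
}

#' Pearson correlation of two logFC trajectories
#'
#' @param a,b Equal-length trajectories (first element 0; see
#'   [logfc_trajectory()]).
#' @return Pearson r, or NA (flagged via attribute `"flagged"`) when either
#'   trajectory has zero variance.
#' @export
trajectory_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), a[1] == 0, b[1] == 0)
  if (anyNA(a) || anyNA(b))
    return(structure(NA_real_, flagged = "incomplete trajectory"))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, flagged = "zero-variance trajectory"))
  stats::cor(a, b)
}

# Wide logFC table (lipids x timepoints) for one tissue/sex from tidy
# differential results.
.logfc_wide <- function(results, timepoints = c("1w", "2w", "4w", "8w")) {
  tw <- results[results$contrast %in% paste0(timepoints, "_vs_SED"), ]
  if (!nrow(tw)) return(NULL)
  wide <- stats::reshape(tw[, c("name", "contrast", "logFC")],
                         idvar = "name", timevar = "contrast",
                         direction = "wide")
  rn <- wide$name
  wide <- as.matrix(wide[, -1, drop = FALSE])
  colnames(wide) <- sub("^logFC\\.", "", colnames(wide))
  rownames(wide) <- rn
  wide[, paste0(timepoints, "_vs_SED"), drop = FALSE]
}

#' Male-female logFC trajectory correlations
#'
#' For each tissue and lipid quantified in both sexes, the Pearson
#' correlation between the male and female 5-point logFC trajectories
#' (0 baseline prepended).
#'
#' @param results Differential results from [run_differential()] (timewise
#'   contrasts, per-sex rows).
#' @param annotations Optional per-tissue annotation list to attach lipid
#'   classes.
#' @return data.frame: `tissue`, `name`, `lipid_class` (NA when unknown), `r`.
#' @export
sex_trajectory_correlations <- function(results, annotations = NULL) {
  out <- list()
  for (tissue in unique(results$tissue)) {
    mw <- .logfc_wide(results[results$tissue == tissue & results$sex == "male", ])
    fw <- .logfc_wide(results[results$tissue == tissue & results$sex == "female", ])
    if (is.null(mw) || is.null(fw)) next
    shared <- intersect(rownames(mw), rownames(fw))
    r <- vapply(shared, function(nm)
      as.numeric(trajectory_correlation(c(0, mw[nm, ]), c(0, fw[nm, ]))), 0)
    cls <- if (!is.null(annotations)) {
      ann <- annotations[[tissue]]
      ann$lipid_class[match(shared, ann$name)]
    } else NA_character_
    out[[tissue]] <- data.frame(tissue = tissue, name = shared,
                                lipid_class = cls, r = unname(r),
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tissue-pair logFC trajectory correlations
#'
#' For each sex and each tissue pair, correlates the 5-point logFC
#' trajectories of lipids (matched by name) present in both tissues.
#'
#' @inheritParams sex_trajectory_correlations
#' @return data.frame: `sex`, `tissue_a`, `tissue_b`, `name`, `r`.
#' @export
tissue_pair_trajectory_correlations <- function(results) {
  out <- list()
  for (sx in setdiff(unique(results$sex), "both")) {
    wides <- list()
    for (tissue in unique(results$tissue))
      wides[[tissue]] <- .logfc_wide(results[results$tissue == tissue &
                                             results$sex == sx, ])
    tissues <- names(wides)[!vapply(wides, is.null, FALSE)]
    if (length(tissues) < 2L) next
    for (i in seq_len(length(tissues) - 1L)) for (j in seq(i + 1L, length(tissues))) {
      a <- wides[[tissues[i]]]; b <- wides[[tissues[j]]]
      shared <- intersect(rownames(a), rownames(b))
      if (!length(shared)) next
      r <- vapply(shared, function(nm)
        as.numeric(trajectory_correlation(c(0, a[nm, ]), c(0, b[nm, ]))), 0)
      out[[length(out) + 1L]] <- data.frame(
        sex = sx, tissue_a = tissues[i], tissue_b = tissues[j], name = shared,
        r = unname(r), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize correlation distributions
#'
#' Per-group medians and binned densities of correlation coefficients, the
#' numeric backing of correlation density panels.
#'
#' @param r Numeric vector of correlations.
#' @param groups data.frame (or vector) of grouping keys aligned with `r`.
#' @param breaks Histogram breaks over `[-1, 1]`.
#' @return List with `medians` (per-group) and `density` (per-group binned
#'   counts).
#' @export
correlation_density_summary <- function(r, groups, breaks = seq(-1, 1, by = 0.1)) {
  if (is.null(dim(groups))) groups <- data.frame(group = groups)
  key <- do.call(paste, c(groups, sep = "|"))
  ok <- is.finite(r)
  stopifnot(any(ok))
  med <- stats::aggregate(r[ok], by = list(group = key[ok]), FUN = stats::median)
  names(med)[2] <- "median_r"
  dens <- lapply(split(r[ok], key[ok]), function(v)
    graphics::hist(v, breaks = breaks, plot = FALSE)$counts)
  list(medians = med, density = dens, breaks = breaks)
}
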