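# Untargeted preprocessing: drift correction, QC filtering, degeneracy
# removal, normalization, sample-outlier screening, cross-tissue PCA and
# variance components; targeted-assay QC with KNN imputation.

#' Extract the study-sample area matrix from a feature table
#'
#' @param table A `feature_table`.
#' @param log2 Return log2 areas.
#' @return Matrix features x animals (columns named by animal id).
#' @export
study_matrix <- function(table, log2 = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  keep <- table$injections$role == "study"
  m <- table$areas[, keep, drop = FALSE]
  colnames(m) <- table$injections$animal_id[keep]
  if (log2) m <- base::log2(m)
  m
}

.qc_matrix <- function(table) {
  keep <- table$injections$role == "QC"
  table$areas[, keep, drop = FALSE]
}

#' Pooled-QC drift correction
#'
#' Per feature, fits an ordinary least-squares line to the pooled-QC peak
#' areas against injection order and divides every area by the fitted value
#' relative to the fit at the reference order (the median QC injection
#' order), so the corrected scale stays near the raw scale. Features with
#' fewer than 3 observed QC areas pass through unchanged; features whose fit
#' goes nonpositive at any study injection are left uncorrected. Both cases
#' are flagged.
#'
#' @param table A `feature_table`.
#' @return The corrected `feature_table`; `$flags$drift_skipped` lists
#'   uncorrected features with the reason.
#' @export
drift_correct <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  qc_cols <- which(table$injections$role == "QC")
  study_cols <- which(table$injections$role == "study")
  ord <- table$injections$order
  skipped <- character(); reason <- character()
  for (i in seq_len(nrow(table$areas))) {
    y <- table$areas[i, qc_cols]
    obs <- is.finite(y)
    if (sum(obs) < 3L) {
      skipped <- c(skipped, table$features$feature_id[i])
      reason <- c(reason, "fewer than 3 QC observations")
      next
    }
    x <- ord[qc_cols][obs]; yv <- y[obs]
    slope <- stats::cov(x, yv) / stats::var(x)
    intercept <- mean(yv) - slope * mean(x)
    ref_fit <- intercept + slope * stats::median(ord[qc_cols])
    fit_all <- intercept + slope * ord
    if (any(fit_all[study_cols] <= 0) || ref_fit <= 0) {
      skipped <- c(skipped, table$features$feature_id[i])
      reason <- c(reason, "nonpositive fitted value")
      next
    }
    table$areas[i, ] <- table$areas[i, ] / (fit_all / ref_fit)
  }
  table$flags$drift_skipped <- data.frame(feature_id = skipped, reason = reason,
                                          stringsAsFactors = FALSE)
  table
}

.qc_cv <- function(table) {
  qc <- .qc_matrix(table)
  apply(qc, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  })
}

#' Quality-control feature filtering
#'
#' Removes features that (1) sit below `blank_ratio` times the blank
#' background (mean blank area, missing treated as 0), (2) are observed in
#' fewer than `qc_presence` of the pooled-QC injections, or (3) exceed
#' `qc_cv_max` coefficient of variation (sd/mean on raw areas) in the pooled
#' QCs.
#'
#' @param table A `feature_table`.
#' @param blank_ratio,qc_presence,qc_cv_max Thresholds (defaults 5, 0.5, 0.30).
#' @return List with the filtered `table` and a `removed` log
#'   (`feature_id`, `rule`).
#' @export
qc_filter <- function(table, blank_ratio = 5, qc_presence = 0.5,
                      qc_cv_max = 0.30) {
  stopifnot(inherits(table, "feature_table"))
  blank_cols <- table$injections$role == "blank"
  qc_cols <- table$injections$role == "QC"
  stopifnot(sum(blank_cols) >= 1L, sum(qc_cols) >= 2L)
  blanks <- table$areas[, blank_cols, drop = FALSE]
  blanks[!is.finite(blanks)] <- 0
  background <- rowMeans(blanks)
  mean_study <- rowMeans(table$areas[, table$injections$role == "study", drop = FALSE],
                         na.rm = TRUE)
  qc <- table$areas[, qc_cols, drop = FALSE]
  presence <- rowMeans(is.finite(qc))
  cv <- .qc_cv(table)

  rule <- rep(NA_character_, nrow(table$areas))
  rule[is.na(rule) & mean_study < blank_ratio * background] <- "blank_ratio"
  rule[is.na(rule) & presence < qc_presence] <- "qc_presence"
  rule[is.na(rule) & (is.na(cv) | cv > qc_cv_max)] <- "qc_cv"
  removed <- data.frame(feature_id = table$features$feature_id[!is.na(rule)],
                        rule = rule[!is.na(rule)], stringsAsFactors = FALSE)
  keep <- is.na(rule)
  table$areas <- table$areas[keep, , drop = FALSE]
  table$features <- table$features[keep, , drop = FALSE]
  rownames(table$features) <- NULL
  list(table = table, removed = removed)
}

#' Remove mode-redundant annotated features
#'
#' Annotated features (MSI 1-3) detected in both ESI modes are de-duplicated
#' by keeping the occurrence with the lower pooled-QC CV; ties keep the
#' positive-mode feature and are flagged.
#'
#' @param pos,neg Positive- and negative-mode `feature_table`s of one tissue.
#' @return List with filtered `positive` and `negative` tables, the `removed`
#'   log and the `ties` flagged.
#' @export
remove_degenerate <- function(pos, neg) {
  stopifnot(inherits(pos, "feature_table"), inherits(neg, "feature_table"))
  cv_pos <- .qc_cv(pos); cv_neg <- .qc_cv(neg)
  annotated <- function(tab) tab$features$msi_level <= 3L
  shared <- intersect(pos$features$name[annotated(pos)],
                      neg$features$name[annotated(neg)])
  drop_pos <- character(); drop_neg <- character(); ties <- character()
  dropped_mode <- character(length(shared))
  for (w in seq_along(shared)) {
    nm <- shared[w]
    ip <- match(nm, pos$features$name); ineg <- match(nm, neg$features$name)
    cp <- cv_pos[ip]; cn <- cv_neg[ineg]
    if (is.na(cp)) cp <- Inf
    if (is.na(cn)) cn <- Inf
    if (cp > cn) {
      drop_pos <- c(drop_pos, pos$features$feature_id[ip])
      dropped_mode[w] <- "positive"
    } else {
      if (cp == cn) ties <- c(ties, nm)
      drop_neg <- c(drop_neg, neg$features$feature_id[ineg])
      dropped_mode[w] <- "negative"
    }
  }
  subset_ft <- function(tab, drop) {
    keep <- !(tab$features$feature_id %in% drop)
    tab$areas <- tab$areas[keep, , drop = FALSE]
    tab$features <- tab$features[keep, , drop = FALSE]
    rownames(tab$features) <- NULL
    tab
  }
  list(positive = subset_ft(pos, drop_pos), negative = subset_ft(neg, drop_neg),
       removed = data.frame(name = shared, dropped_mode = dropped_mode,
                            stringsAsFactors = FALSE),
       ties = ties)
}

#' Normalize a feature table
#'
#' Order of operations: log2-transform, feature-wise standardization to
#' median 0 / sd 1, then sample-wise median-centering. Zero-variance
#' features keep sd 1 and are flagged. Modes are normalized separately;
#' combine with [combine_modes()].
#'
#' @param table A `feature_table`.
#' @return A `normalized_matrix`: list with `values` (lipids x animals),
#'   `features`, `flags`, `tissue`, `esi_mode`.
#' @export
normalize_features <- function(table) {
  m <- study_matrix(table, log2 = TRUE)
  med <- apply(m, 1L, stats::median, na.rm = TRUE)
  sd_f <- apply(m, 1L, stats::sd, na.rm = TRUE)
  flat <- !is.finite(sd_f) | sd_f == 0
  sd_f[flat] <- 1
  v <- (m - med) / sd_f
  samp_med <- apply(v, 2L, stats::median, na.rm = TRUE)
  v <- sweep(v, 2L, samp_med)
  structure(list(values = v, features = table$features,
                 flags = list(zero_variance = table$features$feature_id[flat]),
                 tissue = table$tissue, esi_mode = table$esi_mode),
            class = "normalized_matrix")
}

#' Combine normalized positive- and negative-mode matrices
#' @param ... `normalized_matrix` objects over the same animals.
#' @return A combined `normalized_matrix` (esi_mode `"combined"`).
#' @export
combine_modes <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "normalized_matrix"))
    parts <- parts[[1]]
  parts <- parts[!vapply(parts, is.null, FALSE)]
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, FALSE, "normalized_matrix")))
  cols <- colnames(parts[[1]]$values)
  vals <- do.call(rbind, lapply(parts, function(p) p$values[, cols, drop = FALSE]))
  feats <- do.call(rbind, lapply(parts, `[[`, "features"))
  rownames(feats) <- NULL
  structure(list(values = vals, features = feats,
                 flags = list(zero_variance = unlist(lapply(parts, function(p) p$flags$zero_variance))),
                 tissue = parts[[1]]$tissue, esi_mode = "combined"),
            class = "normalized_matrix")
}

#' Screen for outlier samples
#'
#' Flags a study sample when (a) its median Pearson correlation to the other
#' samples on the raw peak-intensity scale falls below `corr_min`, or (b) a
#' score on one of the first `n_pcs` principal components (retained only when
#' it explains at least `min_pc_var` of variance; PCA on log2
#' feature-standardized data) lies outside `iqr_mult` times the interquartile
#' range. Report only; removal is the caller's decision.
#'
#' @param table A `feature_table`.
#' @param corr_min,iqr_mult,n_pcs,min_pc_var Rule parameters
#'   (defaults 0.75, 3, 3, 0.075).
#' @return data.frame per sample: `animal_id`, `median_cor`, `low_cor`,
#'   `pc_outlier`, `flagged`.
#' @export
detect_outlier_samples <- function(table, corr_min = 0.75, iqr_mult = 3,
                                   n_pcs = 3L, min_pc_var = 0.075) {
  raw <- study_matrix(table)
  stopifnot(ncol(raw) >= 4L)
  cors <- stats::cor(raw, use = "pairwise.complete.obs")
  diag(cors) <- NA
  med_cor <- apply(cors, 2L, stats::median, na.rm = TRUE)

  lg <- log2(raw)
  med <- apply(lg, 1L, stats::median, na.rm = TRUE)
  sd_f <- apply(lg, 1L, stats::sd, na.rm = TRUE)
  sd_f[!is.finite(sd_f) | sd_f == 0] <- 1
  z <- (lg - med) / sd_f
  # PCA needs complete cells; impute the feature median (0 on this scale)
  z[!is.finite(z)] <- 0
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  use <- which(seq_along(ve) <= n_pcs & ve >= min_pc_var)
  pc_out <- rep(FALSE, ncol(raw))
  for (j in use) {
    s <- pc$x[, j]
    q <- stats::quantile(s, c(0.25, 0.75))
    iqr <- q[2] - q[1]
    pc_out <- pc_out | s < q[1] - iqr_mult * iqr | s > q[2] + iqr_mult * iqr
  }
  data.frame(animal_id = colnames(raw), median_cor = med_cor,
             low_cor = med_cor < corr_min, pc_outlier = pc_out,
             flagged = med_cor < corr_min | pc_out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-tissue PCA
#'
#' Builds the lipid x (tissue, sample) matrix over lipids represented in at
#' least `min_tissues` tissues, replaces missing values by each lipid's
#' minimum level, median-centers samples (features deliberately kept on their
#' own scales), and runs PCA with samples as observations.
#'
#' @param matrices Named list (by tissue) of log2 abundance matrices with
#'   lipid names as rownames and animals as columns.
#' @param min_tissues Representation filter (default 5).
#' @return List with `scores` (samples x PC), `loadings`, `var_explained`,
#'   `sample_info` (tissue, animal), `n_lipids`.
#' @export
cross_tissue_pca <- function(matrices, min_tissues = 5L) {
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  lipids <- sort(unique(unlist(lapply(matrices, rownames))))
  rep_count <- rowSums(vapply(matrices, function(m) lipids %in% rownames(m),
                              logical(length(lipids))))
  keep <- lipids[rep_count >= min_tissues]
  if (!length(keep)) stop("no lipid passes the representation filter")
  blocks <- lapply(names(matrices), function(tis) {
    m <- matrices[[tis]]
    out <- matrix(NA_real_, length(keep), ncol(m),
                  dimnames = list(keep, paste(tis, colnames(m), sep = ".")))
    shared <- intersect(keep, rownames(m))
    out[shared, ] <- m[shared, , drop = FALSE]
    out
  })
  big <- do.call(cbind, blocks)
  # min-imputation per lipid
  for (i in seq_len(nrow(big))) {
    v <- big[i, ]
    v[!is.finite(v)] <- min(v[is.finite(v)])
    big[i, ] <- v
  }
  big <- sweep(big, 2L, apply(big, 2L, stats::median))
  pc <- stats::prcomp(t(big), center = TRUE, scale. = FALSE)
  info <- do.call(rbind, lapply(names(matrices), function(tis)
    data.frame(tissue = tis, animal_id = colnames(matrices[[tis]]),
               stringsAsFactors = FALSE)))
  list(scores = pc$x, loadings = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       sample_info = info, n_lipids = length(keep))
}

#' One-way variance components (method of moments)
#'
#' Random-effects decomposition of per-sample scores into between-group and
#' within-group variance: `sigma2_within = MSW`,
#' `sigma2_between = max(0, (MSB - MSW) / n_bar)` with the unbalanced-design
#' average group size `n_bar = (N - sum(n_i^2)/N) / (k - 1)`.
#'
#' @param scores Numeric vector (e.g. one PC's sample scores).
#' @param group Grouping factor (e.g. tissue).
#' @return List with `between_fraction`, `sigma2_between`, `sigma2_within`.
#' @export
variance_components <- function(scores, group) {
  group <- as.factor(droplevels(as.factor(group)))
  stopifnot(length(scores) == length(group))
  n_i <- table(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(n_i < 2L)) stop("singleton groups are not allowed")
  N <- length(scores); k <- nlevels(group)
  gm <- tapply(scores, group, mean)
  msb <- sum(n_i * (gm - mean(scores))^2) / (k - 1)
  msw <- sum((scores - gm[group])^2) / (N - k)
  n_bar <- (N - sum(n_i^2) / N) / (k - 1)
  s2b <- max(0, (msb - msw) / n_bar)
  list(between_fraction = s2b / (s2b + msw), sigma2_between = s2b,
       sigma2_within = msw)
}

# ---- targeted assay ---------------------------------------------------------

#' K-nearest-neighbour imputation over features
#'
#' For each missing cell, averages the values of the `k` features nearest in
#' Euclidean distance over mutually observed samples. When fewer than `k`
#' candidate neighbours exist, the feature's observed mean is used and the
#' cell flagged.
#'
#' @param m Features x samples matrix with missing values.
#' @param k Number of neighbours (default 10).
#' @return List with imputed `values` and logical `fallback` matrix.
#' @export
knn_impute <- function(m, k = 10L) {
  out <- m
  fallback <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  obs <- is.finite(m)
  for (i in which(rowSums(!obs) > 0L)) {
    d <- rep(NA_real_, nrow(m))
    for (j in seq_len(nrow(m))) {
      if (j == i) next
      shared <- obs[i, ] & obs[j, ]
      if (sum(shared) >= 2L)
        d[j] <- sqrt(sum((m[i, shared] - m[j, shared])^2))
    }
    for (s in which(!obs[i, ])) {
      cand <- which(is.finite(d) & obs[, s])
      if (length(cand) < k) {
        out[i, s] <- mean(m[i, obs[i, ]])
        fallback[i, s] <- TRUE
      } else {
        nn <- cand[order(d[cand])][seq_len(k)]
        out[i, s] <- mean(m[nn, s])
      }
    }
  }
  list(values = out, fallback = fallback)
}

#' Targeted-assay quality control and normalization
#'
#' Removes analytes with pooled-QC concentration CV above `conc_cv_max`,
#' retention-time CV above `rt_cv_max`, or more than `miss_max` missing
#' values; imputes the remaining missing cells by feature-KNN; then applies
#' the standard normalization (log2, feature standardization, sample
#' median-centering).
#'
#' @param targeted List with `conc` (analytes x samples), `qc_conc`, `qc_rt`.
#' @param conc_cv_max,rt_cv_max,miss_max Filter thresholds (1.0, 0.10, 0.20).
#' @param k KNN neighbours.
#' @return List with `conc` (imputed), `normalized` (matrix), `removed` log,
#'   `fallback` flags.
#' @export
targeted_qc <- function(targeted, conc_cv_max = 1.0, rt_cv_max = 0.10,
                        miss_max = 0.20, k = 10L) {
  cv <- function(m) apply(m, 1L, function(v) {
    v <- v[is.finite(v)]; if (length(v) < 2L) return(NA_real_)
    stats::sd(v) / mean(v)
  })
  conc_cv <- cv(targeted$qc_conc)
  rt_cv <- cv(targeted$qc_rt)
  miss <- rowMeans(!is.finite(targeted$conc))
  rule <- rep(NA_character_, nrow(targeted$conc))
  rule[is.na(rule) & conc_cv > conc_cv_max] <- "conc_cv"
  rule[is.na(rule) & rt_cv > rt_cv_max] <- "rt_cv"
  rule[is.na(rule) & miss > miss_max] <- "missingness"
  removed <- data.frame(analyte = rownames(targeted$conc)[!is.na(rule)],
                        rule = rule[!is.na(rule)], stringsAsFactors = FALSE)
  conc <- targeted$conc[is.na(rule), , drop = FALSE]
  imp <- knn_impute(conc, k = k)
  lg <- log2(imp$values)
  med <- apply(lg, 1L, stats::median)
  sd_f <- apply(lg, 1L, stats::sd)
  sd_f[!is.finite(sd_f) | sd_f == 0] <- 1
  z <- sweep(sweep(lg, 1L, med), 1L, sd_f, "/")
  z <- sweep(z, 2L, apply(z, 2L, stats::median))
  list(conc = imp$values, normalized = z, removed = removed,
       fallback = imp$fallback)
}
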