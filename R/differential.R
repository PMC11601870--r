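# Per-tissue, per-sex moderated linear-model contrasts with empirical-Bayes
# variance shrinkage: overall training F-test, timewise t-tests vs SED,
# naive sex contrasts, and sex-dimorphic (difference-of-differences)
# response contrasts, with BH FDR.

#' Build a design matrix over training groups
#'
#' @param meta data.frame with a `group` column (and `sex` when
#'   `by_sex_cells`); rows align with the data columns.
#' @param coding `"means"` (one column per cell, no intercept) or
#'   `"mean_reference"` (intercept + non-reference groups).
#' @param groups Group levels in temporal order, reference first.
#' @param by_sex_cells Use sex x group cells (joint two-sex fit).
#' @return Design matrix with full column rank.
#' @export
design_matrix <- function(meta, coding = c("means", "mean_reference"),
                          groups = training_groups(), by_sex_cells = FALSE) {
  coding <- match.arg(coding)
  cell <- if (by_sex_cells) paste(meta$sex, meta$group, sep = ".") else meta$group
  lev <- if (by_sex_cells)
    as.vector(outer(groups, unique(meta$sex), function(g, s) paste(s, g, sep = ".")))
  else groups
  lev <- lev[lev %in% cell]
  f <- factor(cell, levels = lev)
  X <- if (coding == "means") stats::model.matrix(~ 0 + f)
       else stats::model.matrix(~ 1 + f)
  colnames(X) <- sub("^f", "", colnames(X))
  if (coding == "mean_reference") colnames(X)[1] <- "(Intercept)"
  if (qr(X)$rank < ncol(X)) {
    aliased <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  X
}

#' Fit per-lipid linear models
#'
#' Ordinary least squares of each lipid on a shared design, tolerating
#' missing cells (each lipid uses its observed samples; lipids sharing a
#' missingness pattern share the normal-equation inverse).
#'
#' @param values Lipids x samples matrix.
#' @param design Design matrix (samples x coefficients).
#' @return An `lm_fit_set`: `coef` (lipids x coefficients), `s2` residual
#'   variances, `df` residual degrees of freedom, `cov_unscaled` per-pattern
#'   `(X'X)^-1` with `pattern_of` index, and the `design`.
#' @export
fit_linear_models <- function(values, design) {
  stopifnot(is.matrix(values), nrow(design) == ncol(values))
  p <- ncol(design)
  dqr <- qr(design)
  if (dqr$rank < p)
    stop("rank-deficient design; aliased columns: ",
         paste(colnames(design)[dqr$pivot[-seq_len(dqr$rank)]], collapse = ", "))
  obs <- is.finite(values)
  pat_key <- apply(obs, 1L, function(o) paste0("p", paste(which(!o), collapse = ",")))
  pats <- unique(pat_key)
  coef <- matrix(NA_real_, nrow(values), p,
                 dimnames = list(rownames(values), colnames(design)))
  s2 <- rep(NA_real_, nrow(values)); df <- rep(NA_real_, nrow(values))
  covs <- vector("list", length(pats)); names(covs) <- pats
  for (pk in pats) {
    rows <- which(pat_key == pk)
    use <- obs[rows[1], ]
    X <- design[use, , drop = FALSE]
    if (qr(X)$rank < p || sum(use) - p < 1L) next  # unestimable pattern
    xtxi <- chol2inv(chol(crossprod(X)))
    covs[[pk]] <- xtxi
    B <- values[rows, use, drop = FALSE] %*% X %*% xtxi
    fitted <- B %*% t(X)
    rss <- rowSums((values[rows, use, drop = FALSE] - fitted)^2)
    coef[rows, ] <- B
    df[rows] <- sum(use) - p
    s2[rows] <- rss / df[rows]
  }
  structure(list(coef = coef, s2 = s2, df = df, cov_unscaled = covs,
                 pattern_of = pat_key, design = design),
            class = "lm_fit_set")
}

.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  stats::uniroot(function(x) trigamma(x) - y, c(1e-8, 1e8),
                 extendInt = "downX", tol = 1e-10)$root
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method of moments on log residual variances using digamma/trigamma
#' identities: the prior degrees of freedom solve
#' `trigamma(d0/2) = var(e) - mean(trigamma(df/2))` with
#' `e = log(s2) - digamma(df/2) + log(df/2)`, and the prior variance follows
#' from `mean(e)`. A non-positive right-hand side (variances no more
#' dispersed than pure chi-square noise) gives `d0 = Inf`.
#'
#' @param s2 Residual variances (needs >= 10 positive values).
#' @param df Residual degrees of freedom (scalar or per-lipid vector).
#' @return A `moderation_prior`: list with `d0` and `s02`.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df > 0
  if (sum(ok) < 10L) stop("need at least 10 lipids with positive s2")
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  if (stats::var(e) < 1e-12)  # degenerate: all variances identical
    return(structure(list(d0 = Inf, s02 = exp(mean(log(s2[ok])))),
                     class = "moderation_prior"))
  resid_var <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (!is.finite(resid_var) || resid_var <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(resid_var)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s02 = s02), class = "moderation_prior")
}

.posterior_s2 <- function(s2, df, prior) {
  if (is.infinite(prior$d0)) rep_len(prior$s02, length(s2))
  else if (prior$d0 == 0) s2
  else (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
}

#' Moderated t-statistics for one contrast
#'
#' Shrinks each lipid's residual variance toward the prior
#' (`s2_post = (d0 s02 + df s2)/(d0 + df)`) and tests `c'beta = 0` with a
#' t-distribution on `d0 + df` degrees of freedom. With `d0 = 0` this is the
#' classical OLS t-test; with `d0 = Inf` the variance is fully pooled.
#'
#' @param fit An `lm_fit_set`.
#' @param contrast Numeric contrast vector over the design coefficients.
#' @param prior A `moderation_prior`.
#' @return data.frame per lipid: `logFC`, `t`, `df_total`, `p`.
#' @export
moderated_t <- function(fit, contrast, prior) {
  stopifnot(inherits(fit, "lm_fit_set"), length(contrast) == ncol(fit$coef))
  lfc <- as.vector(fit$coef %*% contrast)
  cvc <- vapply(fit$pattern_of, function(pk) {
    V <- fit$cov_unscaled[[pk]]
    if (is.null(V)) NA_real_ else as.numeric(t(contrast) %*% V %*% contrast)
  }, 0)
  s2p <- .posterior_s2(fit$s2, fit$df, prior)
  tstat <- lfc / sqrt(s2p * cvc)
  df_total <- prior$d0 + fit$df
  p <- 2 * stats::pt(-abs(tstat), df_total)
  data.frame(name = rownames(fit$coef), logFC = lfc, t = tstat,
             df_total = df_total, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Moderated F-statistic over a contrast set
#'
#' Combines the moderated t-statistics of linearly independent contrasts
#' into one overall test: the contrast estimates are whitened by the
#' Cholesky factor of their unscaled covariance, giving
#' `F = (C'b)' [C'(X'X)^-1 C]^-1 (C'b) / (k s2_post)` -- the mean of the
#' squared moderated t over the orthogonalized contrasts -- tested against
#' `F(k, d0 + df)`. A single contrast reduces exactly to `t^2`.
#'
#' @param fit An `lm_fit_set`.
#' @param contrasts Matrix (coefficients x k), columns linearly independent.
#' @param prior A `moderation_prior`.
#' @return data.frame per lipid: `F`, `df1`, `df2`, `p`.
#' @export
moderated_F <- function(fit, contrasts, prior) {
  stopifnot(inherits(fit, "lm_fit_set"), nrow(contrasts) == ncol(fit$coef))
  k <- ncol(contrasts)
  if (qr(contrasts)$rank < k) stop("contrasts are linearly dependent")
  est <- fit$coef %*% contrasts
  s2p <- .posterior_s2(fit$s2, fit$df, prior)
  Fstat <- rep(NA_real_, nrow(fit$coef))
  for (pk in unique(fit$pattern_of)) {
    V <- fit$cov_unscaled[[pk]]
    if (is.null(V)) next
    rows <- which(fit$pattern_of == pk)
    Vc <- t(contrasts) %*% V %*% contrasts
    Vci <- chol2inv(chol(Vc))
    q <- rowSums((est[rows, , drop = FALSE] %*% Vci) * est[rows, , drop = FALSE])
    Fstat[rows] <- q / (k * s2p[rows])
  }
  df2 <- prior$d0 + fit$df
  data.frame(name = rownames(fit$coef), F = Fstat, df1 = k, df2 = df2,
             p = stats::pf(Fstat, k, df2, lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values (step-up, monotone).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Contrast vector helper: +1 at `plus`, -1 at `minus` over design columns.
.contrast_vec <- function(design_cols, plus, minus = NULL) {
  v <- stats::setNames(numeric(length(design_cols)), design_cols)
  for (nm in plus) v[nm] <- v[nm] + 1
  for (nm in minus) v[nm] <- v[nm] - 1
  v
}

#' Timewise and overall differential analysis for one sex
#'
#' Fits the means model over training groups (no intercept) on normalized
#' data of one tissue and sex, estimates the variance prior, and returns
#' the per-timepoint contrasts vs SED plus the overall moderated F combining
#' them. BH adjustment is applied within each contrast.
#'
#' @param values Lipids x samples matrix (one tissue, one sex).
#' @param meta data.frame aligned with columns, with `group`.
#' @param groups Group levels, reference first.
#' @param prior Optional `moderation_prior`; estimated from the fit when NULL.
#' @return data.frame: `name`, `contrast` (`"1w_vs_SED"`, ..., `"F_overall"`),
#'   `logFC` (NA for F), `statistic`, `p`, `adj_p`.
#' @export
run_timewise <- function(values, meta, groups = training_groups(), prior = NULL) {
  X <- design_matrix(meta, "means", groups = groups)
  fit <- fit_linear_models(values, X)
  if (is.null(prior)) prior <- estimate_prior(fit$s2, fit$df)
  ref <- groups[1]
  out <- list()
  cs <- list()
  for (g in setdiff(colnames(X), ref)) {
    cv <- .contrast_vec(colnames(X), g, ref)
    cs[[g]] <- cv
    tt <- moderated_t(fit, cv, prior)
    out[[g]] <- data.frame(name = tt$name, contrast = paste0(g, "_vs_", ref),
                           logFC = tt$logFC, statistic = tt$t, p = tt$p,
                           adj_p = bh_adjust(tt$p), stringsAsFactors = FALSE)
  }
  Cmat <- do.call(cbind, cs)
  ff <- moderated_F(fit, Cmat, prior)
  out$F_overall <- data.frame(name = ff$name, contrast = "F_overall",
                              logFC = NA_real_, statistic = ff$F, p = ff$p,
                              adj_p = bh_adjust(ff$p), stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "prior") <- prior
  res
}

#' Sex contrasts from a joint two-sex fit
#'
#' Fits the means model over sex x group cells and emits two families:
#' naive per-timepoint sex differences (male - female within a group) and
#' sex-dimorphic training-response contrasts
#' `(male g - male SED) - (female g - female SED)`. Cells without samples
#' skip the affected contrasts (logged in attribute `"skipped"`).
#'
#' @param values Lipids x samples matrix (both sexes of one tissue).
#' @param meta data.frame aligned with columns, with `sex` and `group`.
#' @param groups Group levels, reference first.
#' @return data.frame as in [run_timewise()], contrasts named
#'   `"male_vs_female_<g>"` and `"dimorphic_<g>"`.
#' @export
sex_contrasts <- function(values, meta, groups = training_groups()) {
  X <- design_matrix(meta, "means", groups = groups, by_sex_cells = TRUE)
  fit <- fit_linear_models(values, X)
  prior <- estimate_prior(fit$s2, fit$df)
  cols <- colnames(X)
  ref <- groups[1]
  have <- function(...) all(c(...) %in% cols)
  out <- list(); skipped <- character()
  for (g in groups) {
    m <- paste0("male.", g); f <- paste0("female.", g)
    if (!have(m, f)) { skipped <- c(skipped, paste0("male_vs_female_", g)); next }
    tt <- moderated_t(fit, .contrast_vec(cols, m, f), prior)
    out[[paste0("naive.", g)]] <- data.frame(
      name = tt$name, contrast = paste0("male_vs_female_", g), logFC = tt$logFC,
      statistic = tt$t, p = tt$p, adj_p = bh_adjust(tt$p), stringsAsFactors = FALSE)
  }
  for (g in setdiff(groups, ref)) {
    m <- paste0("male.", g); f <- paste0("female.", g)
    m0 <- paste0("male.", ref); f0 <- paste0("female.", ref)
    if (!have(m, f, m0, f0)) { skipped <- c(skipped, paste0("dimorphic_", g)); next }
    cv <- .contrast_vec(cols, c(m, f0), c(m0, f))
    tt <- moderated_t(fit, cv, prior)
    out[[paste0("dim.", g)]] <- data.frame(
      name = tt$name, contrast = paste0("dimorphic_", g), logFC = tt$logFC,
      statistic = tt$t, p = tt$p, adj_p = bh_adjust(tt$p), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "prior") <- prior
  res
}

#' Full differential analysis over a study
#'
#' Runs the per-sex timewise analysis and the joint sex contrasts for every
#' tissue of a normalized study (see [preprocess_study()]).
#'
#' @param normalized Named list (tissue) of `normalized_matrix` objects.
#' @param animals Animal metadata (`animal_id`, `sex`, `group`).
#' @param groups Group levels, reference first.
#' @return data.frame with `tissue`, `sex` (`"both"` for sex contrasts),
#'   `name`, `contrast`, `logFC`, `statistic`, `p`, `adj_p`.
#' @export
run_differential <- function(normalized, animals, groups = training_groups()) {
  res <- list()
  for (tissue in names(normalized)) {
    nm <- normalized[[tissue]]
    meta <- animals[match(colnames(nm$values), animals$animal_id), ]
    for (sx in unique(meta$sex)) {
      keep <- meta$sex == sx
      r <- run_timewise(nm$values[, keep, drop = FALSE], meta[keep, ], groups)
      res[[length(res) + 1L]] <- cbind(tissue = tissue, sex = sx, r)
    }
    r <- sex_contrasts(nm$values, meta, groups)
    res[[length(res) + 1L]] <- cbind(tissue = tissue, sex = "both", r)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
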