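# ISTD-based semi-absolute quantification, class-level outlier handling,
# NIPALS imputation, composition summaries, and targeted standard-curve
# calibration.

#' Default internal-standard catalog
#'
#' One deuterated standard per lipid class and ESI mode, spiked into the
#' extraction solvent at a known concentration (values are configuration
#' data inside the 0.1-8 ug/mL spiking range). Classes without their own
#' standard can point at a structurally closest fallback via the
#' `serves_class` column.
#'
#' @return data.frame with `istd_name`, `serves_class`, `esi_mode`,
#'   `conc_ug_ml`, `fallback`.
#' @export
default_istd_catalog <- function() {
  cls <- names(.istd_names)
  data.frame(istd_name = unname(.istd_names),
             serves_class = cls,
             esi_mode = unname(.class_mode[cls]),
             conc_ug_ml = unname(stats::setNames(
               c(2, 2, 1, 1, 1, 0.5, 0.5, 4, 1, 8, 2, 0.5, 0.5, 1, 0.2, 2, 2, 0.5),
               cls)),
             fallback = FALSE, stringsAsFactors = FALSE)
}

#' Semi-absolute quantification against internal standards
#'
#' Converts peak areas to concentrations by ratio to the class- and
#' mode-matched internal standard:
#' `conc = (area / istd_area) * istd_conc * extract_volume / sample_amount`
#' per sample, with the extract volume in uL converted to mL so tissue runs
#' (10 mg in 400 uL solvent) come out in ug/mg and plasma runs (25 uL in
#' 75 uL solvent) in ug/uL. Samples in which a class's ISTD area is missing
#' get that class flagged missing.
#'
#' @param table A `feature_table` (one ESI mode) containing the ISTD features.
#' @param catalog ISTD catalog, see [default_istd_catalog()].
#' @param sample_amount Tissue mass (mg) or plasma volume (uL); default 10.
#' @param extract_volume Extraction solvent volume in uL; default 400.
#' @return A `quant_table`: list with `conc` (lipids x samples), `features`,
#'   `provenance` ("measured"/"missing"), `tissue`, `units`.
#' @export
istd_quantify <- function(table, catalog = default_istd_catalog(),
                          sample_amount = 10, extract_volume = 400) {
  stopifnot(inherits(table, "feature_table"))
  m <- study_matrix(table)
  feats <- table$features
  is_istd <- feats$is_istd
  istd_rows <- which(is_istd)
  if (!length(istd_rows)) stop("no ISTD features present in the table")
  istd_class <- catalog$serves_class[match(feats$name[istd_rows], catalog$istd_name)]
  quant_rows <- which(!is_istd & feats$msi_level <= 3L)
  conc <- matrix(NA_real_, length(quant_rows), ncol(m),
                 dimnames = list(feats$feature_id[quant_rows], colnames(m)))
  prov <- matrix("missing", length(quant_rows), ncol(m),
                 dimnames = dimnames(conc))
  for (w in seq_along(quant_rows)) {
    i <- quant_rows[w]
    ir <- istd_rows[match(feats$lipid_class[i], istd_class)]
    if (is.na(ir)) next  # class with no standard: left missing
    istd_conc <- catalog$conc_ug_ml[match(feats$name[ir], catalog$istd_name)]
    ratio <- m[i, ] / m[ir, ]
    conc[w, ] <- ratio * istd_conc * (extract_volume / 1000) / sample_amount
    prov[w, is.finite(conc[w, ])] <- "measured"
  }
  structure(list(conc = conc, features = feats[quant_rows, , drop = FALSE],
                 provenance = prov, tissue = table$tissue,
                 esi_mode = table$esi_mode,
                 units = if (table$tissue == "plasma") "ug/uL" else "ug/mg"),
            class = "quant_table")
}

#' Combine quantification tables (e.g. the two ESI modes)
#' @param ... `quant_table`s over the same samples.
#' @return A combined `quant_table`.
#' @export
combine_quant <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "quant_table"))
    parts <- parts[[1]]
  parts <- parts[!vapply(parts, is.null, FALSE)]
  cols <- colnames(parts[[1]]$conc)
  feats <- do.call(rbind, lapply(parts, `[[`, "features"))
  rownames(feats) <- NULL
  structure(list(conc = do.call(rbind, lapply(parts, function(p) p$conc[, cols, drop = FALSE])),
                 features = feats,
                 provenance = do.call(rbind, lapply(parts, function(p) p$provenance[, cols, drop = FALSE])),
                 tissue = parts[[1]]$tissue, esi_mode = "combined",
                 units = parts[[1]]$units),
            class = "quant_table")
}

#' Class-sum MAD outlier removal
#'
#' Per lipid class (within one tissue x mode table), computes the per-sample
#' class concentration sum and flags samples whose sum deviates from the
#' median by more than `mad_mult` raw (unscaled) median absolute deviations;
#' for flagged samples the entire class is set missing. A zero MAD with any
#' nonzero deviation flags those samples. Tissues listed in `special`
#' (default WAT-SC) use an override multiplier.
#'
#' @param quant A `quant_table`.
#' @param mad_mult Default multiplier (5).
#' @param special Named overrides, default `c("WAT-SC" = 15)`.
#' @return List with the filtered `quant` and a `removed` log
#'   (`lipid_class`, `animal_id`, `class_sum`).
#' @export
mad_class_filter <- function(quant, mad_mult = 5, special = c("WAT-SC" = 15)) {
  stopifnot(inherits(quant, "quant_table"), ncol(quant$conc) >= 4L)
  mult <- if (quant$tissue %in% names(special)) special[[quant$tissue]] else mad_mult
  removed <- list()
  for (cls in unique(quant$features$lipid_class)) {
    rows <- which(quant$features$lipid_class == cls)
    sums <- colSums(quant$conc[rows, , drop = FALSE], na.rm = TRUE)
    med <- stats::median(sums)
    mad_raw <- stats::median(abs(sums - med))
    dev <- abs(sums - med)
    out <- if (mad_raw == 0) dev > 0 else dev > mult * mad_raw
    if (any(out)) {
      quant$conc[rows, out] <- NA_real_
      quant$provenance[rows, out] <- "removed"
      removed[[length(removed) + 1L]] <- data.frame(
        lipid_class = cls, animal_id = colnames(quant$conc)[out],
        class_sum = sums[out], stringsAsFactors = FALSE)
    }
  }
  list(quant = quant,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(lipid_class = character(), animal_id = character(),
                    class_sum = numeric()))
}

#' NIPALS imputation of missing concentrations
#'
#' Iterative principal-component imputation: rank-`rank` scores and loadings
#' are fitted by alternating least squares whose inner products skip the
#' missing cells, starting from the SVD of the mean-completed matrix, and the
#' missing cells are filled from the converged low-rank reconstruction (for
#' exactly low-rank matrices this is the exact completion). Negative fills
#' are replaced by the feature's observed mean; observed cells are never
#' touched.
#'
#' @param x A `quant_table` or a numeric matrix (features x samples).
#' @param rank Number of components (default 2).
#' @param tol Convergence tolerance on the score vector (default 1e-9).
#' @param max_iter Maximum NIPALS iterations per component (default 500).
#' @return Same type as `x`, imputed. For a `quant_table`, filled cells get
#'   provenance `"imputed"`; non-convergence falls back to the feature mean
#'   and is flagged in `$flags$nipals_fallback`.
#' @export
nipals_impute <- function(x, rank = 2L, tol = 1e-9, max_iter = 500L) {
  m <- if (inherits(x, "quant_table")) x$conc else x
  obs <- is.finite(m)
  if (any(rowMeans(!obs) >= 0.5))
    stop("features with >= 50% missingness must be filtered before imputation")
  if (all(obs)) return(x)
  rmean <- rowSums(m * obs, na.rm = TRUE) / rowSums(obs)
  r <- min(rank, ncol(m) - 1L, nrow(m) - 1L)
  # score/loading alternation over observed cells only: rank-r factors are
  # refit by alternating least squares (each score and loading update uses
  # inner products over the observed cells), initialized from the SVD of the
  # mean-completed matrix; for exactly low-rank data this converges to the
  # exact completion
  work <- m
  work[!obs] <- rmean[row(m)[!obs]]
  sv <- svd(work, nu = r, nv = r)
  A <- sv$u %*% diag(sv$d[seq_len(r)], r)
  B <- sv$v
  converged <- FALSE
  prev <- Inf
  fit_ok <- TRUE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nrow(m))) {
      o <- obs[i, ]
      a <- tryCatch(qr.solve(B[o, , drop = FALSE], m[i, o]),
                    error = function(e) NULL)
      if (is.null(a)) { fit_ok <- FALSE; break }
      A[i, ] <- a
    }
    if (!fit_ok) break
    for (j in seq_len(ncol(m))) {
      o <- obs[, j]
      b <- tryCatch(qr.solve(A[o, , drop = FALSE], m[o, j]),
                    error = function(e) NULL)
      if (is.null(b)) { fit_ok <- FALSE; break }
      B[j, ] <- b
    }
    if (!fit_ok) break
    rss <- sum((m - A %*% t(B))[obs]^2)
    if (abs(prev - rss) < tol * max(1, rss)) { converged <- TRUE; break }
    prev <- rss
  }
  fill <- (A %*% t(B))[!obs]
  fb_mask <- matrix(FALSE, nrow(m), ncol(m))
  if (!converged || !fit_ok || any(!is.finite(fill))) {
    fill <- rmean[row(m)[!obs]]  # feature-mean fallback
    fb_mask[!obs] <- TRUE
  }
  neg <- fill < 0
  fill[neg] <- rmean[row(m)[!obs]][neg]
  m[!obs] <- fill
  if (inherits(x, "quant_table")) {
    x$conc <- m
    x$provenance[!obs] <- "imputed"
    x$flags$nipals_fallback <- any(fb_mask)
    x
  } else m
}

#' Per-sample lipid class composition
#'
#' @param quant A `quant_table` (imputed).
#' @return List with `sums` (class x sample concentration sums) and
#'   `fractions` (columns sum to 1).
#' @export
class_composition <- function(quant) {
  stopifnot(inherits(quant, "quant_table"))
  sums <- rowsum(quant$conc, quant$features$lipid_class, na.rm = TRUE)
  fractions <- sweep(sums, 2L, colSums(sums), "/")
  list(sums = sums, fractions = fractions)
}

#' Per-sample PC:PE concentration ratio
#'
#' Summed phosphatidylcholine over summed phosphatidylethanolamine
#' concentration (ether classes O-PC/O-PE excluded). Samples with zero PE
#' sum are returned as NA with a flag attribute.
#'
#' @param quant A `quant_table`.
#' @return Named numeric vector per sample, attribute `"flagged"`.
#' @export
pcpe_ratio <- function(quant) {
  stopifnot(inherits(quant, "quant_table"))
  pc <- colSums(quant$conc[quant$features$lipid_class == "PC", , drop = FALSE],
                na.rm = TRUE)
  pe <- colSums(quant$conc[quant$features$lipid_class == "PE", , drop = FALSE],
                na.rm = TRUE)
  bad <- pe == 0
  r <- pc / pe
  r[bad] <- NA_real_
  attr(r, "flagged") <- names(r)[bad]
  r
}

#' Per-sample, per-class DHA:ARA ratio
#'
#' For each class (PC and PE by default), the ratio of summed concentrations
#' of 22:6-containing species to 20:4-containing species, where species
#' qualify only when the PUFA chain is paired with a 16:0/16:1/18:0/18:1
#' anchor chain ([select_pufa_species()]). Sum-level species are skipped and
#' reported.
#'
#' @param quant A `quant_table`.
#' @param annotations Annotation data.frame with a `chains` list-column
#'   covering `quant`'s features.
#' @param classes Classes to evaluate.
#' @return List per class of per-sample ratios (NA + flag when the ARA
#'   selection is empty); attribute `"skipped"` from the species selection.
#' @export
dha_ara_ratio <- function(quant, annotations, classes = c("PC", "PE")) {
  stopifnot(inherits(quant, "quant_table"))
  sel <- select_pufa_species(annotations, classes = classes)
  out <- list()
  for (cls in classes) {
    dha_ids <- sel$feature_id[sel$lipid_class == cls & sel$target == "22:6"]
    ara_ids <- sel$feature_id[sel$lipid_class == cls & sel$target == "20:4"]
    dha <- colSums(quant$conc[rownames(quant$conc) %in% dha_ids, , drop = FALSE],
                   na.rm = TRUE)
    ara <- colSums(quant$conc[rownames(quant$conc) %in% ara_ids, , drop = FALSE],
                   na.rm = TRUE)
    r <- dha / ara
    r[!length(ara_ids) | ara == 0] <- NA_real_
    out[[cls]] <- r
  }
  attr(out, "skipped") <- attr(sel, "skipped")
  out
}

#' Standard-curve calibration for targeted analytes
#'
#' Fits an ordinary least-squares line of response area on standard
#' concentration; curves with R squared below `r2_min` are rejected and the
#' analyte marked uncalibrated. Unknown areas are back-calculated through
#' the curve; negative back-calculations are floored at 0 and flagged.
#'
#' @param standards data.frame with columns `conc` and `area` (>= 3 points).
#' @param unknowns Numeric vector of unknown areas.
#' @param r2_min Minimal acceptable R squared (default 0.9).
#' @return List with `calibrated` (logical), `r_squared`, `slope`,
#'   `intercept`, `conc` (back-calculated, NULL when rejected) and `floored`
#'   indices.
#' @export
calibrate_targeted <- function(standards, unknowns, r2_min = 0.9) {
  stopifnot(is.data.frame(standards), nrow(standards) >= 3L,
            all(c("conc", "area") %in% names(standards)))
  fit <- stats::lm(area ~ conc, data = standards)
  tss <- sum((standards$area - mean(standards$area))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  if (!is.finite(r2) || r2 < r2_min)
    return(list(calibrated = FALSE, r_squared = r2, slope = NA, intercept = NA,
                conc = NULL, floored = integer()))
  b <- stats::coef(fit)
  conc <- (unknowns - b[[1]]) / b[[2]]
  floored <- which(conc < 0)
  conc[floored] <- 0
  list(calibrated = TRUE, r_squared = r2, slope = b[[2]], intercept = b[[1]],
       conc = conc, floored = floored)
}
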