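# Study-level drivers: preprocessing, quantification, and the full
# simulate -> preprocess -> quantify -> differential -> enrichment ->
# clustering -> network pipeline used by the analysis scripts.

#' Preprocess every tissue of a study
#'
#' Per tissue and ESI mode: pooled-QC drift correction, QC filtering
#' (blank ratio, QC presence, QC CV), mode-degeneracy removal, outlier-sample
#' screening, then normalization (log2, feature standardization, sample
#' median-centering) per mode and row-concatenation of the modes. The
#' normalized matrices carry annotated lipids only (MSI 1-3, internal
#' standards excluded), keyed by lipid name; the cleaned feature tables
#' (standards included) are returned for quantification.
#'
#' @param study A `lipid_study` from [simulate_study()] (or the same shape).
#' @return List with `normalized` (per tissue `normalized_matrix`),
#'   `tables` (per tissue, per mode cleaned `feature_table`s),
#'   `outliers` (per tissue reports), `logs` (removal logs).
#' @export
preprocess_study <- function(study) {
  normalized <- list(); tables <- list(); outliers <- list(); logs <- list()
  for (tissue in names(study$tables)) {
    modes <- study$tables[[tissue]]
    cleaned <- list(); removed <- list()
    for (mode in names(modes)) {
      tab <- drift_correct(modes[[mode]])
      qf <- qc_filter(tab)
      cleaned[[mode]] <- qf$table
      removed[[mode]] <- qf$removed
    }
    if (all(c("positive", "negative") %in% names(cleaned))) {
      dg <- remove_degenerate(cleaned$positive, cleaned$negative)
      cleaned$positive <- dg$positive
      cleaned$negative <- dg$negative
      removed$degenerate <- dg$removed
    }
    outliers[[tissue]] <- lapply(cleaned, detect_outlier_samples)
    parts <- lapply(cleaned, function(tab) {
      keep <- tab$features$msi_level <= 3L & !tab$features$is_istd
      tab$areas <- tab$areas[keep, , drop = FALSE]
      tab$features <- tab$features[keep, , drop = FALSE]
      normalize_features(tab)
    })
    nm <- combine_modes(parts)
    rn <- nm$features$name
    stopifnot(!anyDuplicated(rn))
    rownames(nm$values) <- rn
    normalized[[tissue]] <- nm
    tables[[tissue]] <- cleaned
    logs[[tissue]] <- removed
  }
  list(normalized = normalized, tables = tables, outliers = outliers,
       logs = logs)
}

#' Quantify every tissue of a preprocessed study
#'
#' ISTD semi-absolute quantification per mode (tissue runs: 10 mg in 400 uL
#' solvent; plasma: 25 uL in 75 uL solvent), mode combination, class-sum MAD
#' outlier removal (5 MAD, 15 for WAT-SC), removal of features over the
#' missingness ceiling, then NIPALS imputation.
#'
#' @param tables Per-tissue, per-mode cleaned feature tables
#'   (from [preprocess_study()]).
#' @param catalog ISTD catalog.
#' @param nipals_rank Components for the imputation (default 2).
#' @param max_missing Features above this missing fraction are dropped
#'   before imputation (default 0.5, the imputation's validity limit).
#' @return List with `quant` (per tissue `quant_table`, keyed by name) and
#'   `logs`.
#' @export
quantify_study <- function(tables, catalog = default_istd_catalog(),
                           nipals_rank = 2L, max_missing = 0.5) {
  quant <- list(); logs <- list()
  for (tissue in names(tables)) {
    parts <- lapply(tables[[tissue]], function(tab) {
      if (tissue == "plasma")
        istd_quantify(tab, catalog, sample_amount = 25, extract_volume = 75)
      else istd_quantify(tab, catalog, sample_amount = 10, extract_volume = 400)
    })
    q <- combine_quant(parts)
    rownames(q$conc) <- q$features$name
    rownames(q$provenance) <- q$features$name
    mf <- mad_class_filter(q)
    q <- mf$quant
    too_missing <- rowMeans(!is.finite(q$conc)) >= max_missing
    if (any(too_missing)) {
      q$conc <- q$conc[!too_missing, , drop = FALSE]
      q$provenance <- q$provenance[!too_missing, , drop = FALSE]
      q$features <- q$features[!too_missing, , drop = FALSE]
    }
    q <- nipals_impute(q, rank = nipals_rank)
    quant[[tissue]] <- q
    logs[[tissue]] <- list(mad_removed = mf$removed,
                           dropped_missing = names(too_missing)[too_missing])
  }
  list(quant = quant, logs = logs)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulates a study and takes it through preprocessing, quantification,
#' differential analysis, lipid-set enrichment (overall-F LSEA per tissue
#' and sex), fuzzy c-means trajectory clustering with core ORA, male-female
#' trajectory correlations, cross-tissue correlation networks per sex, and
#' signed-TOM modules with phenotype correlations. Every random stage is
#' seeded from `seed`, so identical seeds give identical output objects.
#'
#' @param seed Master seed.
#' @param design A [study_design()].
#' @param effects Planted effects (default [default_effect_panel()]).
#' @param n_lipids Lipids per tissue.
#' @param n_perm LSEA permutations (default 1000 here; the methods default
#'   of 10000 applies to one-off set tests, not the tissue sweep).
#' @param cluster_c Cluster number for the trajectory stage (default 9).
#' @param tom_beta Soft power for the module stage (default 6).
#' @param stages Character subset of
#'   `c("quantify", "enrichment", "cluster", "trajcorr", "network", "modules",
#'   "targeted")` to run beyond simulate/preprocess/differential.
#' @return List with the stage outputs (`sim`, `pre`, `quant`, `diff`,
#'   `enrich`, `clusters`, `cluster_ora`, `sex_trajcorr`, `networks`,
#'   `modules`, `module_phenotype`, `targeted`) and `truth_eval`
#'   (sensitivity and empirical FDR against the planted truth).
#' @export
run_study_pipeline <- function(seed = 1L, design = study_design(),
                               effects = default_effect_panel(),
                               n_lipids = 600L, n_perm = 1000L,
                               lsea_min_size = 10L, cluster_c = 9L,
                               tom_beta = 6L,
                               stages = c("quantify", "enrichment", "cluster",
                                          "trajcorr", "network", "modules",
                                          "targeted")) {
  seed <- as.integer(seed)
  sim <- simulate_study(design = design, effects = effects,
                        n_lipids = n_lipids, seed = seed)
  pre <- preprocess_study(sim)
  diff <- run_differential(pre$normalized, design$animals)
  out <- list(sim = sim, pre = pre, diff = diff)
  out$truth_eval <- truth_report(sim$truth, diff[diff$sex %in% design$sexes &
                                                 diff$contrast == "F_overall", ])

  if ("quantify" %in% stages)
    out$quant <- quantify_study(pre$tables)

  if ("enrichment" %in% stages) {
    enr <- list()
    for (tissue in names(pre$normalized)) {
      ann <- sim$annotations[[tissue]]
      ann <- ann[match(rownames(pre$normalized[[tissue]]$values), ann$name), ]
      sets <- split(ann$name, ann$lipid_class)
      for (sx in design$sexes) {
        fo <- diff[diff$tissue == tissue & diff$sex == sx &
                   diff$contrast == "F_overall", ]
        metric <- stats::setNames(fo$statistic, fo$name)
        metric <- metric[is.finite(metric)]
        res <- tryCatch(lsea(metric, sets, n_perm = n_perm,
                             min_size = lsea_min_size, score_type = "pos",
                             seed = seed + 101L),
                        error = function(e) NULL)
        if (!is.null(res))
          enr[[paste(tissue, sx, sep = ".")]] <- cbind(tissue = tissue, sex = sx, res)
      }
    }
    out$enrich <- if (length(enr)) do.call(rbind, enr)
    rownames(out$enrich) <- NULL
  }

  if ("cluster" %in% stages || "trajcorr" %in% stages) {
    clusters <- list(); cluster_ora <- list()
    for (tissue in names(pre$normalized)) {
      nm <- pre$normalized[[tissue]]
      meta <- design$animals[match(colnames(nm$values), design$animals$animal_id), ]
      tm <- trajectory_matrix(nm$values, meta, design$groups)
      if ("cluster" %in% stages && nrow(tm) > cluster_c) {
        fit <- cmeans_fuzzy(tm, c = cluster_c, seed = seed + 202L)
        clusters[[tissue]] <- fit
        ann <- sim$annotations[[tissue]]
        sets <- split(ann$name[ann$msi_level <= 3L & !ann$is_istd],
                      ann$lipid_class[ann$msi_level <= 3L & !ann$is_istd])
        background <- rownames(tm)
        oras <- list()
        for (k in seq_len(fit$c)) {
          core <- rownames(tm)[fit$core[, k]]
          if (length(core) < 3L) next
          o <- ora_catalog(core, sets, background)
          oras[[length(oras) + 1L]] <- cbind(cluster = k, o)
        }
        if (length(oras)) cluster_ora[[tissue]] <- do.call(rbind, oras)
      }
    }
    out$clusters <- clusters
    out$cluster_ora <- cluster_ora
  }

  if ("trajcorr" %in% stages)
    out$sex_trajcorr <- sex_trajectory_correlations(diff[diff$sex %in% design$sexes, ],
                                                    sim$annotations)

  if ("network" %in% stages) {
    networks <- list()
    for (sx in design$sexes) {
      ids <- design$animals$animal_id[design$animals$sex == sx]
      mats <- lapply(pre$normalized, function(nm)
        nm$values[, colnames(nm$values) %in% ids, drop = FALSE])
      networks[[sx]] <- build_correlation_network(mats)
    }
    out$networks <- networks
  }

  if ("modules" %in% stages) {
    modules <- list(); mod_ph <- list()
    for (tissue in names(pre$normalized)) {
      v <- pre$normalized[[tissue]]$values
      tom <- tom_similarity(v, beta = tom_beta)
      ms <- detect_modules(tom, v)
      modules[[tissue]] <- ms
      if (!is.null(ms$eigenprofiles))
        mod_ph[[tissue]] <- module_phenotype_correlation(ms, sim$phenotypes)
    }
    out$modules <- modules
    out$module_phenotype <- mod_ph
  }

  if ("targeted" %in% stages) {
    targ <- list()
    for (tissue in names(sim$targeted)) {
      tq <- targeted_qc(sim$targeted[[tissue]])
      meta <- design$animals[match(colnames(tq$normalized),
                                   design$animals$animal_id), ]
      res <- list()
      for (sx in design$sexes) {
        keep <- meta$sex == sx
        r <- tryCatch(run_timewise(tq$normalized[, keep, drop = FALSE],
                                   meta[keep, ], design$groups),
                      error = function(e) NULL)
        if (!is.null(r)) res[[sx]] <- cbind(tissue = tissue, sex = sx, r)
      }
      targ[[tissue]] <- list(qc = tq, diff = if (length(res)) do.call(rbind, res))
    }
    out$targeted <- targ
  }
  out
}
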