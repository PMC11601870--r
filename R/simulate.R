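# Synthetic multi-tissue lipidomics studies with planted ground truth.
#
# Emulates the endurance-training design: 8 tissues + plasma, 2 sexes,
# groups SED/1w/2w/4w/8w with n animals per cell, untargeted feature tables
# per tissue x ESI mode (with pooled-QC and blank injections, injection-order
# drift, intensity-dependent missingness, spiked internal standards),
# a targeted oxylipin/NAE concentration table, and matched phenotypes whose
# temporal templates follow the training study (body fat falling in males,
# NEFA rising then falling, VO2max rising).

#' Default study compartments
#' @return Character vector of the nine compartments (eight tissues + plasma).
#' @export
default_tissues <- function() {
  c("BAT", "heart", "HIPPOC", "kidney", "liver", "lung", "plasma",
    "SKM-GN", "WAT-SC")
}

#' Training groups in temporal order
#' @return `c("SED", "1w", "2w", "4w", "8w")`.
#' @export
training_groups <- function() c("SED", "1w", "2w", "4w", "8w")

#' Define a study design
#'
#' @param tissues Compartment names (default nine incl. plasma).
#' @param sexes Default male/female.
#' @param groups Training groups, sedentary first.
#' @param n_per_cell Animals per sex x group cell (default 5). Animal ids are
#'   shared across tissues.
#' @return A `study_design`: list with the arguments plus an `animals`
#'   data.frame (`animal_id`, `sex`, `group`).
#' @export
study_design <- function(tissues = default_tissues(),
                         sexes = c("male", "female"),
                         groups = training_groups(),
                         n_per_cell = 5L) {
  stopifnot(n_per_cell >= 2L, length(groups) >= 2L)
  animals <- expand.grid(rep_i = seq_len(n_per_cell), group = groups,
                         sex = sexes, stringsAsFactors = FALSE)
  animals$animal_id <- sprintf("%s%02d", ifelse(animals$sex == "male", "M", "F"),
                               seq_len(nrow(animals) / length(sexes)))
  animals <- animals[, c("animal_id", "sex", "group")]
  structure(list(tissues = tissues, sexes = sexes, groups = groups,
                 n_per_cell = n_per_cell, animals = animals),
            class = "study_design")
}

# ---- lipid universe ---------------------------------------------------------

.class_mode <- c(PC = "positive", LPC = "positive", SM = "positive",
                 TAG = "positive", DAG = "positive", Car = "positive",
                 CE = "positive", NAE = "positive", "O-PC" = "positive",
                 PE = "negative", "O-PE" = "negative", PS = "negative",
                 PI = "negative", PG = "negative", LPE = "negative",
                 FFA = "negative", Cer = "negative", HexCer = "negative")

.istd_names <- c(PC = "PC 15:0_18:1(d7)", PE = "PE 15:0_18:1(d7)",
                 PS = "PS 15:0_18:1(d7)", PG = "PG 15:0_18:1(d7)",
                 PI = "PI 15:0_18:1(d7)", LPC = "LPC 18:1(d7)",
                 LPE = "LPE 18:1(d7)", CE = "CE 18:1(d7)",
                 DAG = "DAG 15:0_18:1(d7)", TAG = "TAG 15:0_18:1_15:0(d7)",
                 SM = "SM d36:1(d9)", Cer = "Cer C17:0(d7)",
                 Car = "Car 16:0(d7)", FFA = "FFA 17:0(d7)",
                 NAE = "NAE 16:0(d7)", "O-PC" = "PC O-16:0_18:1(d7)",
                 "O-PE" = "PE O-16:0_18:1(d7)", HexCer = "HexCer d35:1(d7)")

# Chain pools for chain-resolved phospholipid names; anchors first so the
# DHA:ARA selections are well populated.
.anchor_pool <- c("16:0", "16:1", "18:0", "18:1")
.partner_pool <- c("20:4", "22:6", "18:2", "20:3", "22:5", "20:5", "18:1", "16:0")

.make_names <- function(class, n, kind) {
  if (n <= 0L) return(character())
  switch(kind,
    tag_sum = {
      grid <- expand.grid(C = seq(32L, 60L, by = 2L), D = 0:8)
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE][seq_len(min(n, nrow(grid))), ]
      sprintf("TAG %d:%d", grid$C, grid$D)
    },
    chain_pair = {
      grid <- expand.grid(a = .anchor_pool, b = .partner_pool,
                          stringsAsFactors = FALSE)
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE][seq_len(min(n, nrow(grid))), ]
      sprintf("%s %s_%s", class, grid$a, grid$b)
    },
    ether_pair = {
      grid <- expand.grid(a = c("O-16:0", "O-18:1", "P-16:0", "P-18:0"),
                          b = .partner_pool, stringsAsFactors = FALSE)
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE][seq_len(min(n, nrow(grid))), ]
      sprintf("%s %s_%s", sub("^O-", "", class), grid$a, grid$b)
    },
    sum2 = {
      grid <- expand.grid(C = seq(30L, 44L, by = 1L), D = 0:6)
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE][seq_len(min(n, nrow(grid))), ]
      sprintf("%s %d:%d", class, grid$C, grid$D)
    },
    sphingo_sum = {
      grid <- expand.grid(C = 30:44, D = 0:3)
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE][seq_len(min(n, nrow(grid))), ]
      sprintf("%s d%d:%d", class, grid$C, grid$D)
    },
    acyl = {
      grid <- expand.grid(C = 12:26, D = 0:2)
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE][seq_len(min(n, nrow(grid))), ]
      sprintf(if (class == "Cer") "Cer C%d:%d" else paste(class, "%d:%d"),
              grid$C, grid$D)
    })
}

# Per-class target counts for a universe of ~n lipids (scaled). The TAG share
# is raised in the adipose compartments, whose lipid mass is TAG-dominated.
.universe_plan <- function(n, tissue) {
  base <- c(TAG = 110, PC = 80, PE = 55, `O-PE` = 28, `O-PC` = 14, PS = 18,
            PI = 16, PG = 12, LPC = 24, LPE = 14, SM = 34, Cer = 24,
            HexCer = 12, Car = 26, CE = 12, FFA = 18, DAG = 24, NAE = 10)
  if (tissue %in% c("WAT-SC", "BAT")) base["TAG"] <- 150
  round(base * n / sum(base))
}

.simulate_universe <- function(n_lipids, tissue, n_junk, n_shared_modes = 6L) {
  plan <- .universe_plan(n_lipids, tissue)
  kinds <- c(TAG = "tag_sum", PC = "chain_pair", PE = "chain_pair",
             `O-PE` = "ether_pair", `O-PC` = "ether_pair", PS = "sum2",
             PI = "sum2", PG = "sum2", LPC = "acyl", LPE = "acyl",
             SM = "sphingo_sum", Cer = "acyl", HexCer = "sphingo_sum",
             Car = "acyl", CE = "acyl", FFA = "acyl", DAG = "sum2",
             NAE = "acyl")
  feats <- list()
  for (cls in names(plan)) {
    nm <- unique(.make_names(cls, plan[[cls]], kinds[[cls]]))
    if (!length(nm)) next
    feats[[cls]] <- data.frame(name = nm, lipid_class = cls,
                               esi_mode = .class_mode[[cls]], msi_level = 2L,
                               is_istd = FALSE, stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, feats)
  # a handful of species detected in both ESI modes (degeneracy removal work)
  shared <- feats[feats$lipid_class == "PC", ][seq_len(n_shared_modes), ]
  shared$esi_mode <- "negative"
  feats <- rbind(feats, shared)
  # internal standards, one per class per mode
  istd <- data.frame(name = unname(.istd_names[names(plan)]),
                     lipid_class = names(plan),
                     esi_mode = unname(.class_mode[names(plan)]),
                     msi_level = 1L, is_istd = TRUE, stringsAsFactors = FALSE)
  # unannotated junk features that the QC filters should catch
  junk <- if (n_junk > 0L)
    data.frame(name = sprintf("unknown_%03d", seq_len(n_junk)),
               lipid_class = NA_character_,
               esi_mode = sample(c("positive", "negative"), n_junk, TRUE),
               msi_level = 4L, is_istd = FALSE, stringsAsFactors = FALSE)
    else NULL
  feats <- rbind(feats, istd, junk)
  feats$feature_id <- sprintf("%s_%s_%04d", tissue, substr(feats$esi_mode, 1, 3),
                              seq_len(nrow(feats)))
  rownames(feats) <- NULL
  feats
}

# ---- effects ----------------------------------------------------------------

#' Specify a planted effect
#'
#' @param kind One of `"sex_baseline"` (male-minus-female shift applied to all
#'   groups), `"timewise"` (per-timepoint shift vs SED, same in both sexes
#'   unless `sexes` restricts it), `"sex_by_time"` (per-timepoint shift applied
#'   only to `sexes`, creating a sex-dimorphic training response).
#' @param classes,ids Lipid selector: classes and/or explicit feature names;
#'   at least one must resolve to a lipid.
#' @param size For `"sex_baseline"` a scalar; otherwise a vector named by the
#'   non-SED groups. Sizes are standardized: multiples of the within-cell
#'   noise SD on the log2 scale.
#' @param sexes Sexes the effect applies to.
#' @param tissues Tissues the effect applies to (default all).
#' @param fraction Fraction of matching lipids that receive the effect.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(kind = c("timewise", "sex_baseline", "sex_by_time"),
                        classes = NULL, ids = NULL, size,
                        sexes = c("male", "female"), tissues = NULL,
                        fraction = 1) {
  kind <- match.arg(kind)
  stopifnot(all(is.finite(size)), fraction > 0, fraction <= 1)
  structure(list(kind = kind, classes = classes, ids = ids, size = size,
                 sexes = sexes, tissues = tissues, fraction = fraction),
            class = "effect_spec")
}

#' Default planted-effect panel
#'
#' Encodes the qualitative patterns the study reports: a biphasic TAG response
#' (up at 1-2w, down by 8w) in liver/adipose/muscle, an early acylcarnitine
#' rise in lung/liver/plasma mirrored by a fall in heart, a female-higher
#' baseline for DHA-containing phospholipids, and a male-only heart response.
#'
#' @param groups Non-SED groups in order.
#' @return List of [effect_spec()]s.
#' @export
default_effect_panel <- function(groups = c("1w", "2w", "4w", "8w")) {
  sz <- function(...) stats::setNames(c(...), groups)
  list(
    effect_spec("timewise", classes = "TAG", size = sz(3, 2.5, -1, -3),
                tissues = c("liver", "WAT-SC", "SKM-GN", "BAT"), fraction = 0.5),
    effect_spec("timewise", classes = "Car", size = sz(3.5, 3, 1.5, 0.5),
                tissues = c("lung", "liver", "plasma"), fraction = 0.7),
    effect_spec("timewise", classes = "Car", size = sz(-3.5, -3, -1.5, -0.5),
                tissues = "heart", fraction = 0.7),
    effect_spec("sex_baseline", classes = c("PC", "PE"), size = -2,
                tissues = c("kidney", "liver", "heart", "SKM-GN", "plasma"),
                fraction = 0.3),
    effect_spec("sex_by_time", classes = c("PC", "PE", "O-PE"),
                size = sz(1.5, 2, 2.5, 3), sexes = "male",
                tissues = "heart", fraction = 0.3)
  )
}

.resolve_effect <- function(spec, features, tissue) {
  if (!is.null(spec$tissues) && !(tissue %in% spec$tissues)) return(character())
  sel <- rep(FALSE, nrow(features))
  if (!is.null(spec$classes))
    sel <- sel | (features$lipid_class %in% spec$classes & !features$is_istd)
  if (!is.null(spec$ids)) sel <- sel | features$name %in% spec$ids
  ids <- features$name[sel]
  ids <- unique(ids)
  if (spec$fraction < 1 && length(ids))
    ids <- sort(sample(ids, max(1L, round(length(ids) * spec$fraction))))
  ids
}

# ---- main generator ---------------------------------------------------------

#' Simulate a multi-tissue lipidomics study
#'
#' Generates untargeted feature tables (one per tissue x ESI mode) with
#' pooled-QC injections at every tenth position, blank injections,
#' per-feature linear injection-order drift, intensity-dependent missingness
#' and spiked internal standards; a targeted oxylipin/NAE table with QC
#' replicates; per-animal phenotypes; and the full ground truth.
#'
#' Peak areas follow a lognormal model:
#' `area = 2^(baseline + effects + latent module factors + animal noise) *
#' drift(order)`, with per-feature drift slopes drawn Normal(0, `drift_sd`).
#' Class-block latent factors per animal give the data co-expression module
#' structure, and the phenotype table is linearly linked to the adipose TAG
#' latent so module-phenotype correlations have known sign.
#'
#' @param design A [study_design()].
#' @param effects List of [effect_spec()]s (possibly empty for a null study).
#' @param n_lipids Approximate annotated lipids per tissue.
#' @param noise_sd Within-cell SD of log2 abundance (default 0.25, approx.
#'   19\% CV); effect sizes are multiples of this.
#' @param missing_rate Overall fraction of study cells set missing
#'   (intensity-dependent; must be < 0.5).
#' @param drift_sd SD of per-feature linear drift slope per injection.
#' @param n_junk Unannotated features planted to fail the QC filters.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `lipid_study`: list with `design`, `tables` (per tissue, lists
#'   with `$positive`/`$negative` feature tables), `annotations` (per tissue),
#'   `targeted` (per tissue), `phenotypes`, and `truth` (a `ground_truth`).
#' @export
simulate_study <- function(design = study_design(),
                           effects = default_effect_panel(),
                           n_lipids = 600L, noise_sd = 0.25,
                           missing_rate = 0.05, drift_sd = 0.002,
                           n_junk = 24L, seed = 1L) {
  stopifnot(inherits(design, "study_design"), noise_sd > 0,
            missing_rate >= 0, missing_rate < 0.5)
  set.seed(as.integer(seed))
  animals <- design$animals
  n_anim <- nrow(animals)
  groups <- design$groups

  # per-animal latent module factors (shared loading within a class block):
  # biological animal-to-animal variation that creates co-expression and
  # phenotype structure; acts as ordinary animal-level noise for any single
  # lipid's group contrasts
  latent <- list(TAG = stats::rnorm(n_anim), PL = stats::rnorm(n_anim))
  loadings <- c(TAG = 1.0, PL = 0.8)  # in units of noise_sd

  tables <- list(); annotations <- list(); targeted <- list()
  truth_mu <- list(); truth_drift <- list(); truth_planted <- list()
  truth_junk <- list(); module_labels <- list()
  spec_hits <- integer(length(effects))

  for (tissue in design$tissues) {
    feats <- .simulate_universe(n_lipids, tissue, n_junk)
    nfeat <- nrow(feats)
    baseline <- stats::rnorm(nfeat, mean = 18, sd = 2)
    # adipose TAG dominates total lipid mass
    hi <- feats$lipid_class %in% "TAG" & tissue %in% c("WAT-SC", "BAT")
    baseline[hi] <- baseline[hi] + 7
    baseline[feats$is_istd] <- 20
    baseline[feats$msi_level == 4L] <- stats::rnorm(sum(feats$msi_level == 4L), 12, 1)

    # true cell means: lipids x (sex.group)
    cells <- expand.grid(group = groups, sex = design$sexes,
                         stringsAsFactors = FALSE)
    cell_key <- paste(cells$sex, cells$group, sep = ".")
    shift <- matrix(0, nfeat, nrow(cells), dimnames = list(feats$name, cell_key))
    planted <- list()
    for (si in seq_along(effects)) {
      spec <- effects[[si]]
      ids <- .resolve_effect(spec, feats, tissue)
      spec_hits[si] <- spec_hits[si] + length(ids)
      if (!length(ids)) next
      ridx <- match(ids, feats$name)
      for (ci in seq_len(nrow(cells))) {
        sx <- cells$sex[ci]; gr <- cells$group[ci]
        delta <- switch(spec$kind,
          sex_baseline = if (sx %in% spec$sexes)
            (if (sx == "male") 0.5 else -0.5) * spec$size * noise_sd else 0,
          timewise = if (gr != "SED" && sx %in% spec$sexes)
            spec$size[[gr]] * noise_sd else 0,
          sex_by_time = if (gr != "SED" && sx %in% spec$sexes)
            spec$size[[gr]] * noise_sd else 0)
        shift[ridx, ci] <- shift[ridx, ci] + delta
      }
      planted[[length(planted) + 1L]] <- data.frame(
        tissue = tissue, name = ids, kind = spec$kind,
        sexes = paste(spec$sexes, collapse = "+"),
        max_abs_size = max(abs(spec$size)), stringsAsFactors = FALSE)
    }
    mu <- baseline + shift  # recycles baseline down columns
    truth_mu[[tissue]] <- mu
    truth_planted[[tissue]] <- if (length(planted)) do.call(rbind, planted) else
      data.frame(tissue = character(), name = character(), kind = character(),
                 sexes = character(), max_abs_size = numeric())
    truth_junk[[tissue]] <- feats$feature_id[feats$msi_level == 4L]
    module_labels[[tissue]] <- ifelse(feats$lipid_class %in% "TAG", "TAG-block",
                               ifelse(feats$lipid_class %in% c("PC", "PE", "O-PC", "O-PE"),
                                      "PL-block", "none"))
    names(module_labels[[tissue]]) <- feats$name

    # animal-level true log2 values
    acell <- match(paste(animals$sex, animals$group, sep = "."), cell_key)
    x_true <- mu[, acell, drop = FALSE]
    for (blk in names(latent)) {
      rows <- if (blk == "TAG") feats$lipid_class %in% "TAG"
              else feats$lipid_class %in% c("PC", "PE", "O-PC", "O-PE")
      x_true[rows, ] <- x_true[rows, ] +
        loadings[[blk]] * noise_sd * matrix(rep(latent[[blk]], each = sum(rows)),
                                            nrow = sum(rows))
    }
    dimnames(x_true) <- list(feats$name, animals$animal_id)

    tissue_tables <- list(); tissue_drift <- list()
    for (mode in c("positive", "negative")) {
      fsub <- feats[feats$esi_mode == mode, , drop = FALSE]
      if (!nrow(fsub)) next
      tab <- .build_feature_table(fsub, x_true[fsub$name, , drop = FALSE],
                                  animals, tissue, mode, noise_sd,
                                  missing_rate, drift_sd)
      tissue_tables[[mode]] <- tab$table
      tissue_drift[[mode]] <- tab$drift_slopes
    }
    tables[[tissue]] <- tissue_tables
    truth_drift[[tissue]] <- tissue_drift
    annotations[[tissue]] <- feats
    targeted[[tissue]] <- .simulate_targeted(animals, tissue, noise_sd)
  }

  applicable <- vapply(effects, function(spec)
    is.null(spec$tissues) || any(spec$tissues %in% design$tissues), FALSE)
  if (any(applicable & spec_hits == 0L))
    stop("effect selector ", which(applicable & spec_hits == 0L)[1],
         " resolved to zero lipids in every tissue")

  phen <- .simulate_phenotypes(animals, latent)
  truth <- structure(list(design = design, group_means = truth_mu,
                          drift_slopes = truth_drift, planted = truth_planted,
                          junk_features = truth_junk,
                          module_labels = module_labels, latent = latent,
                          phenotype_links = phen$links, noise_sd = noise_sd,
                          seed = as.integer(seed)),
                     class = "ground_truth")
  structure(list(design = design, tables = tables, annotations = annotations,
                 targeted = targeted, phenotypes = phen$table, truth = truth),
            class = "lipid_study")
}

.build_feature_table <- function(feats, x_true, animals, tissue, mode,
                                 noise_sd, missing_rate, drift_sd) {
  n_anim <- nrow(animals)
  study_order <- sample.int(n_anim)  # injection randomization
  # layout: blank, then study injections with a pooled QC every 10th position
  roles <- c("blank"); samp <- c(NA_character_)
  qc_i <- 0L
  for (i in seq_len(n_anim)) {
    if ((length(roles) %% 10L) == 0L) { roles <- c(roles, "QC"); samp <- c(samp, NA) }
    roles <- c(roles, "study")
    samp <- c(samp, animals$animal_id[study_order[i]])
  }
  roles <- c(roles, "QC", "blank"); samp <- c(samp, NA, NA)
  inj <- data.frame(injection_id = sprintf("%s_%s_inj%03d", tissue,
                                           substr(mode, 1, 3), seq_along(roles)),
                    order = seq_along(roles), role = roles, animal_id = samp,
                    stringsAsFactors = FALSE)
  inj$sex <- animals$sex[match(inj$animal_id, animals$animal_id)]
  inj$group <- animals$group[match(inj$animal_id, animals$animal_id)]

  nfeat <- nrow(feats)
  slopes <- stats::rnorm(nfeat, 0, drift_sd)
  ref <- stats::median(inj$order)
  drift <- 1 + outer(slopes, inj$order - ref)  # nfeat x ninj
  drift[drift < 0.2] <- 0.2

  areas <- matrix(NA_real_, nfeat, nrow(inj),
                  dimnames = list(feats$feature_id, inj$injection_id))
  is_study <- inj$role == "study"
  noise <- matrix(stats::rnorm(nfeat * sum(is_study), 0, noise_sd), nfeat)
  x_meas <- x_true[, inj$animal_id[is_study], drop = FALSE] + noise
  areas[, is_study] <- 2^x_meas

  pooled <- rowMeans(2^x_true)  # pooled QC = equal-part mix of study samples
  is_qc <- inj$role == "QC"
  qc_noise <- matrix(stats::rnorm(nfeat * sum(is_qc), 0, 0.07), nfeat)
  areas[, is_qc] <- pooled * 2^qc_noise

  is_blank <- inj$role == "blank"
  blank_level <- pooled / 2^8  # ~0.4% carryover background
  junk <- feats$msi_level == 4L
  blank_level[junk] <- pooled[junk] / 2  # junk: fails the 5x blank rule
  areas[, is_blank] <- blank_level * 2^matrix(stats::rnorm(nfeat * sum(is_blank), 0, 0.3), nfeat)
  # half the junk features instead fail the QC-CV rule
  if (any(junk)) {
    noisy <- which(junk)[seq_len(ceiling(sum(junk) / 2))]
    blank_level[noisy] <- pooled[noisy] / 2^8
    areas[noisy, is_blank] <- blank_level[noisy] *
      2^matrix(stats::rnorm(length(noisy) * sum(is_blank), 0, 0.3), length(noisy))
    areas[noisy, is_qc] <- pooled[noisy] *
      2^matrix(stats::rnorm(length(noisy) * sum(is_qc), 0, 0.8), length(noisy))
  }
  areas <- areas * drift

  # intensity-dependent missingness on study + QC cells (ISTDs exempt)
  if (missing_rate > 0) {
    cells <- which(!is_blank[col(areas)] & !feats$is_istd[row(areas)])
    x_all <- log2(areas[cells])
    z <- (x_all - mean(x_all)) / stats::sd(x_all)
    a <- stats::uniroot(function(a) mean(stats::plogis(a - 1.5 * z)) - missing_rate,
                        c(-30, 30))$root
    miss <- stats::runif(length(cells)) < stats::plogis(a - 1.5 * z)
    areas[cells[miss]] <- NA_real_
  }

  table <- structure(list(areas = areas, features = feats, injections = inj,
                          tissue = tissue, esi_mode = mode, flags = list()),
                     class = "feature_table")
  list(table = table, drift_slopes = stats::setNames(slopes, feats$feature_id))
}

# Targeted oxylipin/NAE panel: concentrations (ng/mg or ng/100uL) with pooled
# QC replicates for concentration and retention time, plus planted failures
# for each targeted-QC rule.
.simulate_targeted <- function(animals, tissue, noise_sd) {
  analytes <- c("12,13-DiHOME", "9,10-DiHOME", "13-HODE", "9-HODE", "5-HETE",
                "12-HETE", "15-HETE", "20-HETE", "14,15-DiHET", "PGE2",
                "TXB2", "AEA", "OEA", "PEA", "DHEA", "LEA", "SEA", "2-AG")
  k <- length(analytes)
  n <- nrow(animals)
  base <- stats::runif(k, 0.5, 20)
  conc <- matrix(base * 2^stats::rnorm(k * n, 0, noise_sd * 1.6), k, n,
                 dimnames = list(analytes, animals$animal_id))
  # NAE training response: OEA/PEA rise at early timepoints
  up <- analytes %in% c("OEA", "PEA", "AEA")
  tp_shift <- c(SED = 0, `1w` = 0.6, `2w` = 0.5, `4w` = 0.25, `8w` = 0)
  conc[up, ] <- conc[up, ] * 2^rep(tp_shift[animals$group], each = sum(up))
  n_qc <- 6L
  qc_conc <- matrix(base * 2^stats::rnorm(k * n_qc, 0, 0.15), k, n_qc,
                    dimnames = list(analytes, sprintf("QC%d", seq_len(n_qc))))
  rt <- stats::runif(k, 2, 14)
  qc_rt <- matrix(rt * exp(stats::rnorm(k * n_qc, 0, 0.01)), k, n_qc,
                  dimnames = dimnames(qc_conc))
  # planted failures: one high conc CV, one high RT CV, one >20% missing
  qc_conc[1, ] <- base[1] * 2^stats::rnorm(n_qc, 0, 2.5)
  qc_rt[2, ] <- rt[2] * exp(stats::rnorm(n_qc, 0, 0.25))
  conc[3, sample.int(n, ceiling(0.3 * n))] <- NA_real_
  # light random missingness elsewhere
  drop <- which(stats::runif(k * n) < 0.03)
  conc[setdiff(drop, which(row(conc) <= 3))] <- NA_real_
  list(conc = conc, qc_conc = qc_conc, qc_rt = qc_rt, tissue = tissue,
       failing = stats::setNames(analytes[1:3],
                                 c("conc_cv", "rt_cv", "missingness")))
}

# Phenotype templates follow the training study qualitatively: males lose fat
# and gain fitness strongly, NEFA/glycerol rise early then return, leptin
# tracks adiposity. The %fat and leptin values are linked to the adipose TAG
# latent factor so module-phenotype correlations have planted sign.
.simulate_phenotypes <- function(animals, latent) {
  g <- animals$group; male <- animals$sex == "male"
  tp <- function(male_v, female_v)
    ifelse(male, male_v[match(g, training_groups())],
           female_v[match(g, training_groups())])
  n <- nrow(animals)
  lat_tag <- latent$TAG; lat_pl <- latent$PL
  tab <- data.frame(
    animal_id = animals$animal_id, sex = animals$sex, group = g,
    body_weight = tp(c(380, 376, 372, 365, 355), c(210, 209, 208, 206, 204)) +
      stats::rnorm(n, 0, 8),
    pct_fat = tp(c(18, 17, 16, 14.5, 13), c(16, 15.8, 15.5, 15.2, 15)) +
      1.2 * lat_tag + stats::rnorm(n, 0, 0.8),
    nefa = tp(c(0.50, 0.80, 0.75, 0.62, 0.52), c(0.55, 0.78, 0.72, 0.62, 0.56)) +
      0.06 * lat_tag + stats::rnorm(n, 0, 0.05),
    glycerol = tp(c(0.25, 0.38, 0.35, 0.30, 0.26), c(0.27, 0.37, 0.34, 0.30, 0.28)) +
      stats::rnorm(n, 0, 0.03),
    glucose = tp(c(160, 156, 152, 148, 145), c(150, 148, 146, 144, 142)) +
      stats::rnorm(n, 0, 6),
    leptin = tp(c(9, 8.2, 7.5, 6.3, 5.2), c(6.5, 6.3, 6.1, 5.9, 5.7)) +
      0.9 * lat_tag + stats::rnorm(n, 0, 0.5),
    vo2max = tp(c(62, 66, 69, 73, 77), c(68, 70, 72, 74, 76)) -
      1.5 * lat_pl + stats::rnorm(n, 0, 2.5),
    max_speed = tp(c(28, 30, 32, 34, 36), c(30, 31, 32, 34, 35)) +
      stats::rnorm(n, 0, 1.5),
    adipocyte_area = tp(c(3200, 3050, 2900, 2650, 2400), c(2800, 2760, 2720, 2680, 2650)) +
      150 * lat_tag + stats::rnorm(n, 0, 120),
    adipocyte_count = tp(c(95, 99, 103, 110, 118), c(100, 101, 103, 105, 107)) +
      stats::rnorm(n, 0, 5),
    stringsAsFactors = FALSE)
  links <- data.frame(
    phenotype = c("pct_fat", "nefa", "leptin", "adipocyte_area", "vo2max"),
    latent = c("TAG", "TAG", "TAG", "TAG", "PL"),
    sign = c(1, 1, 1, 1, -1), stringsAsFactors = FALSE)
  list(table = tab, links = links)
}

# ---- truth reporting --------------------------------------------------------

#' Score differential results against the planted truth
#'
#' A lipid counts as planted (for one tissue and sex) when any nonzero
#' timewise or sex-by-time effect was applied to it for that sex; it counts
#' as discovered when any of its timewise contrasts passes the FDR cut.
#'
#' @param truth A `ground_truth` from [simulate_study()].
#' @param results Contrast results data.frame with columns `tissue`, `sex`,
#'   `name`, `adj_p` — one contrast family, typically the overall training
#'   F-test (the study's definition of a training-responsive lipid) or a
#'   single timewise family.
#' @param fdr FDR cut (default 0.05).
#' @return List with `sensitivity`, `empirical_fdr`, and the per-lipid call
#'   table. No discoveries gives `empirical_fdr = 0`.
#' @export
truth_report <- function(truth, results, fdr = 0.05) {
  stopifnot(inherits(truth, "ground_truth"),
            all(c("tissue", "sex", "name", "adj_p") %in% names(results)))
  calls <- stats::aggregate(adj_p ~ tissue + sex + name, data = results,
                            FUN = min, na.rm = TRUE)
  calls$discovered <- calls$adj_p < fdr
  planted_keys <- character()
  for (tissue in names(truth$planted)) {
    pl <- truth$planted[[tissue]]
    pl <- pl[pl$kind %in% c("timewise", "sex_by_time"), , drop = FALSE]
    if (!nrow(pl)) next
    for (i in seq_len(nrow(pl))) {
      for (sx in strsplit(pl$sexes[i], "+", fixed = TRUE)[[1]])
        planted_keys <- c(planted_keys, paste(tissue, sx, pl$name[i], sep = "\r"))
    }
  }
  planted_keys <- unique(planted_keys)
  key <- paste(calls$tissue, calls$sex, calls$name, sep = "\r")
  truth_universe <- unlist(lapply(names(truth$group_means),
                                  function(t) rownames(truth$group_means[[t]])))
  if (!all(calls$name %in% truth_universe))
    stop("results contain lipids absent from the ground truth universe")
  calls$planted <- key %in% planted_keys
  n_planted_tested <- sum(calls$planted)
  n_disc <- sum(calls$discovered)
  sens <- if (n_planted_tested) sum(calls$discovered & calls$planted) / n_planted_tested else NA_real_
  efdr <- if (n_disc) sum(calls$discovered & !calls$planted) / n_disc else 0
  list(sensitivity = sens, empirical_fdr = efdr, calls = calls)
}
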