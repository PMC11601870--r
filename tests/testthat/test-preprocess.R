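# Drift correction, QC filters, degeneracy removal, normalization,
# outlier screening, cross-tissue PCA, variance components, targeted QC.

test_that("drift correction matches the closed-form OLS worked example", {
  # QC areas 100,120,140 at orders 1,5,9: slope 5, intercept 95, reference
  # fit at the median QC order (5) is 120; a study area of 140 at order 9
  # corrects to 140 / (140/120) = 120.
  areas <- rbind(c(100, 150, 120, 130, 140, 140))
  roles <- c("QC", "study", "QC", "study", "QC", "study")
  tab <- make_feature_table(areas, roles, orders = c(1, 2, 5, 7, 9, 9))
  out <- drift_correct(tab)
  expect_equal(out$areas[1, 6], 120)
  expect_identical(nrow(out$flags$drift_skipped), 0L)
})

test_that("drift correction leaves zero-slope features unchanged and flags thin QCs", {
  areas <- rbind(constant = c(100, 88, 100, 97, 100, 91),
                 thin = c(100, 88, NA, 97, 100, 91))
  roles <- c("QC", "study", "QC", "study", "QC", "study")
  tab <- make_feature_table(areas, roles)
  out <- drift_correct(tab)
  expect_equal(out$areas[1, ], tab$areas[1, ])       # constant QCs: identity
  expect_equal(out$areas[2, ], tab$areas[2, ])       # < 3 QC obs: untouched
  expect_identical(out$flags$drift_skipped$reason, "fewer than 3 QC observations")
})

test_that("drift correction does not inflate QC CV on simulated linear drift", {
  des <- study_design(tissues = "liver")
  sim <- simulate_study(des, effects = list(), n_lipids = 120,
                        drift_sd = 0.004, seed = 21)
  tab <- sim$tables$liver$positive
  cv <- function(t) apply(t$areas[, t$injections$role == "QC"], 1, function(v) {
    v <- v[is.finite(v)]; stats::sd(v) / mean(v)
  })
  before <- cv(tab); after <- cv(drift_correct(tab))
  expect_lte(stats::median(after - before, na.rm = TRUE), 0)
})

test_that("qc_filter applies the blank, presence and CV rules exactly", {
  # rows: kept; low vs blank; absent from QCs; high QC CV (50,150 -> 70.7%)
  areas <- rbind(keep = c(5, 1000, 1000, 1000, 1000, 5),
                 blankish = c(10, 40, 40, 40, 40, 10),
                 sparse = c(0.1, 900, NA, 900, NA, 0.1),
                 wobbly = c(0.1, 800, 50, 800, 150, 0.1))
  roles <- c("blank", "study", "QC", "study", "QC", "blank")
  tab <- make_feature_table(areas, roles)
  out <- qc_filter(tab)
  expect_identical(out$table$features$name, "lip1")
  expect_identical(out$removed$rule[match(c("liver_pos_0002", "liver_pos_0003",
                                            "liver_pos_0004"),
                                          out$removed$feature_id)],
                   c("blank_ratio", "qc_presence", "qc_cv"))
  # a feature observed in 3 of 4 QCs with CV 0 is kept
  areas2 <- rbind(c(0.1, 500, 100, 500, 100, NA, 100, 0.1))
  roles2 <- c("blank", "study", "QC", "study", "QC", "QC", "QC", "blank")
  out2 <- qc_filter(make_feature_table(areas2, roles2))
  expect_identical(nrow(out2$removed), 0L)
  # idempotent
  again <- qc_filter(out$table)
  expect_identical(again$table$areas, out$table$areas)
  expect_identical(nrow(again$removed), 0L)
})

test_that("degeneracy removal keeps the lower-CV mode and breaks ties positive", {
  mk <- function(qc, mode, name) {
    areas <- rbind(c(1, 500, qc[1], 500, qc[2], 1))
    make_feature_table(areas, c("blank", "study", "QC", "study", "QC", "blank"),
                       names = name, esi_mode = mode)
  }
  pos <- mk(c(100, 120), "positive", "PC 34:1")
  neg <- mk(c(100, 160), "negative", "PC 34:1")
  out <- remove_degenerate(pos, neg)
  expect_identical(nrow(out$positive$features), 1L)
  expect_identical(nrow(out$negative$features), 0L)
  expect_identical(out$removed$dropped_mode, "negative")
  # tie: positive kept, flagged
  out2 <- remove_degenerate(mk(c(100, 120), "positive", "PC 34:1"),
                            mk(c(200, 240), "negative", "PC 34:1"))
  expect_identical(nrow(out2$negative$features), 0L)
  expect_identical(out2$ties, "PC 34:1")
  # unique names untouched
  out3 <- remove_degenerate(mk(c(100, 120), "positive", "PC 34:1"),
                            mk(c(100, 120), "negative", "PE 34:2"))
  expect_identical(nrow(out3$positive$features), 1L)
  expect_identical(nrow(out3$negative$features), 1L)
})

test_that("normalization matches a hand-computed 3x3 fixture and centres exactly", {
  # log2 areas: rows lipids, cols samples
  lg <- rbind(c(1, 2, 3), c(2, 2, 5), c(4, 6, 6))
  areas <- 2^lg
  tab <- make_feature_table(cbind(areas, 1), c("study", "study", "study", "QC"))
  tab$areas[, 4] <- NA
  nm <- normalize_features(tab)
  med <- apply(lg, 1, median); s <- apply(lg, 1, sd)
  z <- (lg - med) / s
  expected <- sweep(z, 2, apply(z, 2, median))
  expect_equal(unname(nm$values), unname(expected), tolerance = 1e-12)
  # feature medians exactly 0 pre-centering; sample medians exactly 0 after
  expect_true(all(abs(apply(z, 1, median)) < 1e-12))
  expect_true(all(abs(apply(nm$values, 2, median)) < 1e-12))
})

test_that("zero-variance features are zeroed and flagged, not dropped", {
  # rows 2 and 3 mirror each other, so sample medians are 0 and the constant
  # feature stays exactly 0 after both normalization steps
  areas <- rbind(c(8, 8, 8), c(2, 4, 16), c(16, 4, 2))
  tab <- make_feature_table(areas, rep("study", 3))
  nm <- normalize_features(tab)
  expect_true(all(nm$values[1, ] == 0))
  expect_identical(nm$flags$zero_variance, "liver_pos_0001")
})

test_that("outlier screening flags a planted shift and passes clean duplicates", {
  set.seed(42)
  profile <- rnorm(60, 15, 3)                 # shared abundance profile
  base <- matrix(2^(profile + rnorm(60 * 12, 0, 0.4)), 60, 12)
  base[, 2] <- base[, 1]                      # exact duplicate: not an outlier
  out_tab <- base
  out_tab[, 12] <- 2^(profile + 20 * 0.4 + rnorm(60, 0, 0.4))  # +20 sd shift
  tab <- make_feature_table(out_tab, rep("study", 12))
  rep_ <- detect_outlier_samples(tab)
  expect_true(rep_$flagged[12])
  expect_false(any(rep_$flagged[1:2]))
  # clean data: no flags expected at 3x IQR
  tab0 <- make_feature_table(matrix(2^(profile + rnorm(60 * 12, 0, 0.4)), 60, 12),
                             rep("study", 12))
  expect_identical(sum(detect_outlier_samples(tab0)$flagged), 0L)
})

test_that("cross-tissue PCA applies the representation filter and min-imputation", {
  set.seed(1)
  lipids <- sprintf("L%02d", 1:30)
  mats <- lapply(1:6, function(i) {
    keep <- if (i <= 2) lipids[1:20] else lipids          # L21.. in 4 of 6
    m <- matrix(rnorm(length(keep) * 4, 15), length(keep), 4,
                dimnames = list(keep, paste0("A", 1:4)))
    m
  })
  names(mats) <- paste0("T", 1:6)
  pc <- cross_tissue_pca(mats, min_tissues = 5)
  expect_identical(pc$n_lipids, 20L)
  expect_identical(nrow(pc$scores), 24L)
  expect_error(cross_tissue_pca(mats, min_tissues = 7), "representation")
  # two identical tissues separate by nothing
  two <- list(A = mats$T3, B = mats$T3)
  pc2 <- cross_tissue_pca(two, min_tissues = 2)
  d <- pc2$scores[1:4, 1] - pc2$scores[5:8, 1]
  expect_true(all(abs(d) < 1e-10))
})

test_that("variance components reproduce closed-form ANOVA and the two limits", {
  # balanced two-group fixture with known MSB/MSW
  x <- c(1, 2, 3, 7, 8, 9); g <- rep(c("a", "b"), each = 3)
  vc <- variance_components(x, g)
  msb <- 3 * sum((tapply(x, g, mean) - mean(x))^2) / 1
  msw <- sum((x - rep(tapply(x, g, mean), each = 3))^2) / 4
  s2b <- (msb - msw) / 3
  expect_equal(vc$between_fraction, s2b / (s2b + msw), tolerance = 1e-12)
  # identical within-group values, distinct means: 100% between
  vc2 <- variance_components(c(1, 1, 5, 5), c("a", "a", "b", "b"))
  expect_equal(vc2$between_fraction, 1)
  # random labels on iid data: near-zero between fraction (simulation)
  set.seed(9)
  fr <- replicate(40, variance_components(rnorm(40), rep(1:4, each = 10))$between_fraction)
  expect_lt(median(fr), 0.1)
  expect_error(variance_components(1:3, c("a", "a", "b")), "ingleton")
})

test_that("targeted QC removes the planted failures and KNN copies a twin", {
  des <- study_design(tissues = "liver")
  sim <- simulate_study(des, n_lipids = 60, seed = 13)
  targ <- sim$targeted$liver
  out <- targeted_qc(targ)
  expect_setequal(out$removed$analyte, unname(targ$failing))
  expect_identical(unname(out$removed$rule[match(targ$failing, out$removed$analyte)]),
                   names(targ$failing))
  expect_false(anyNA(out$conc))
  expect_true(all(abs(apply(out$normalized, 2, median)) < 1e-12))
  # k = 1 with an identical twin feature imputes the twin's value
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 5, 2, 8))
  m["a", 2] <- NA
  imp <- knn_impute(m, k = 1)
  expect_equal(unname(imp$values["a", 2]), 2)
  # fewer than k candidate neighbours: feature-mean fallback, flagged
  imp2 <- knn_impute(m, k = 5)
  expect_equal(unname(imp2$values["a", 2]), mean(c(1, 3, 4)))
  expect_true(imp2$fallback["a", 2])
})
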