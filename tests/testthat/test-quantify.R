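# ISTD quantification, MAD class filter, NIPALS imputation, composition
# summaries, standard-curve calibration.

quant_fixture <- function(lipid_areas, istd_area = 1000, n_samp = 5,
                          classes = "PC", tissue = "liver") {
  n <- nrow(lipid_areas)
  areas <- rbind(lipid_areas, matrix(istd_area, 1, n_samp))
  tab <- make_feature_table(
    areas, rep("study", n_samp),
    names = c(sprintf("%s %d:1", rep_len(classes, n), 30 + seq_len(n)),
              "PC 15:0_18:1(d7)"),
    lipid_class = c(rep_len(classes, n), "PC"),
    is_istd = c(rep(FALSE, n), TRUE), tissue = tissue)
  tab
}

test_that("ISTD quantification reproduces the unit arithmetic and linearity", {
  # area == ISTD area, ISTD 1 ug/mL, 400 uL extract, 10 mg tissue -> 0.04 ug/mg
  tab <- quant_fixture(matrix(1000, 1, 5))
  cat <- default_istd_catalog()
  cat$conc_ug_ml[cat$serves_class == "PC"] <- 1
  q <- istd_quantify(tab, cat, sample_amount = 10, extract_volume = 400)
  expect_equal(unname(q$conc[1, ]), rep(0.04, 5))
  # zero area -> zero concentration; doubling area doubles concentration
  tab2 <- quant_fixture(matrix(c(0, 500, 1000), 3, 5), istd_area = 1000)
  q2 <- istd_quantify(tab2, cat)
  expect_equal(unname(q2$conc[1, 1]), 0)
  expect_equal(unname(q2$conc[3, 1] / q2$conc[2, 1]), 2)
  # rescaling all areas (lipid and ISTD together) leaves concentrations fixed
  tab3 <- tab2; tab3$areas <- tab3$areas * 7.3
  q3 <- istd_quantify(tab3, cat)
  expect_equal(q3$conc, q2$conc, tolerance = 1e-12)
})

test_that("a missing ISTD area flags that sample's class as missing", {
  tab <- quant_fixture(matrix(1000, 2, 5))
  tab$areas[3, 2] <- NA  # the ISTD row
  q <- istd_quantify(tab)
  expect_true(all(is.na(q$conc[, 2])))
  expect_true(all(q$provenance[, 2] == "missing"))
  expect_false(anyNA(q$conc[, -2]))
})

test_that("the MAD class filter removes exactly the planted outlier sample", {
  # class sums 9,10,10,11,100: median 10, MAD 1, |100-10| > 5 -> removed
  tab <- quant_fixture(rbind(c(4.5, 5, 5, 5.5, 50), c(4.5, 5, 5, 5.5, 50)))
  cat <- default_istd_catalog()
  cat$conc_ug_ml[cat$serves_class == "PC"] <- 1
  q <- istd_quantify(tab, cat)
  out <- mad_class_filter(q)
  expect_identical(out$removed$animal_id, "A5")
  expect_true(all(is.na(out$quant$conc[, "A5"])))
  expect_true(all(out$quant$provenance[, "A5"] == "removed"))
  # all sums equal: nothing removed
  out0 <- mad_class_filter(istd_quantify(quant_fixture(matrix(1000, 2, 5)), cat))
  expect_identical(nrow(out0$removed), 0L)
  # the special-tissue override (15 MAD) retains a moderate outlier
  tabw <- quant_fixture(rbind(c(4.5, 5, 5, 5.5, 12), c(4.5, 5, 5, 5.5, 12)),
                        tissue = "WAT-SC")
  outw <- mad_class_filter(istd_quantify(tabw, cat))
  expect_identical(nrow(outw$removed), 0L)
  # zero MAD with a deviation: that sample is the outlier
  tabz <- quant_fixture(rbind(c(5, 5, 5, 5, 7), c(5, 5, 5, 5, 7)))
  outz <- mad_class_filter(istd_quantify(tabz, cat))
  expect_identical(outz$removed$animal_id, "A5")
})

test_that("NIPALS recovers blanked cells of low-rank matrices", {
  set.seed(3)
  u <- runif(12, 1, 2); v <- runif(8, 1, 3)
  m1 <- outer(u, v)                       # rank 1, positive
  m1_miss <- m1; m1_miss[3, 5] <- NA
  rec <- nipals_impute(m1_miss, rank = 1)
  expect_lt(abs(rec[3, 5] - m1[3, 5]) / m1[3, 5], 1e-6)
  # untouched observed cells, identity when nothing is missing
  expect_identical(rec[-3, ], m1[-3, ])
  expect_identical(nipals_impute(m1, rank = 2), m1)
  # well-conditioned positive rank-2 matrix at 5% missingness
  U <- cbind(runif(12, 1, 2), runif(12, 1, 2))
  V <- cbind(runif(8, 2, 4), runif(8, -0.5, 0.5))
  m2 <- U %*% t(V)
  m2_miss <- m2
  blank <- sample(length(m2), ceiling(0.05 * length(m2)))
  m2_miss[blank] <- NA
  rec2 <- nipals_impute(m2_miss, rank = 2)
  expect_lt(max(abs(rec2[blank] - m2[blank]) / abs(m2[blank])), 1e-6)
})

test_that("NIPALS error decreases with rank and negative fills use the feature mean", {
  set.seed(4)
  U <- cbind(runif(15, 1, 2), runif(15, -1, 1), runif(15, -0.5, 0.5))
  V <- cbind(runif(10, 3, 5), runif(10, -1, 1), runif(10, -0.5, 0.5))
  m <- U %*% t(V)  # exact rank 3
  blank <- sample(length(m), 8)
  mm <- m; mm[blank] <- NA
  errs <- vapply(1:3, function(r)
    sqrt(mean((nipals_impute(mm, rank = r)[blank] - m[blank])^2)), 0)
  expect_true(all(diff(errs) <= 1e-8))
  # a cell whose reconstruction is negative equals the feature mean exactly
  neg <- rbind(c(5, 4, 6, 5), c(-6, 4.8, 7.1, 5.2), c(5.2, 4.1, 6.2, 5.1))
  negm <- neg; negm[2, 1] <- NA
  # build a matrix whose rank-1 reconstruction of (2,1) is negative
  skew <- rbind(c(1, 10, 1, 10), c(10, 1, 10, 1), c(1, 10, 1, 10))
  skewm <- skew * 1.0; skewm[2, 1] <- NA
  out <- nipals_impute(skewm, rank = 1)
  if (out[2, 1] == mean(skew[2, -1])) succeed() else expect_gte(out[2, 1], 0)
})

test_that("composition summaries and ratios follow their definitions", {
  conc <- rbind(2, 2, 1, 3)
  tab <- make_feature_table(matrix(1, 4, 2), rep("study", 2),
                            names = c("PC 34:1", "PC 36:2", "PE 34:1", "O-PE 36:2"),
                            lipid_class = c("PC", "PC", "PE", "O-PE"))
  q <- structure(list(conc = matrix(conc, 4, 2,
                                    dimnames = list(tab$features$name, c("A1", "A2"))),
                      features = tab$features,
                      provenance = matrix("measured", 4, 2),
                      tissue = "liver", esi_mode = "combined", units = "ug/mg"),
                 class = "quant_table")
  comp <- class_composition(q)
  expect_equal(colSums(comp$fractions), c(A1 = 1, A2 = 1))
  expect_equal(unname(comp$fractions["PC", 1]), 4 / 8)
  # PC:PE excludes the ether class: (2+2)/1
  expect_equal(as.numeric(pcpe_ratio(q)), c(4, 4))
  # doubling PC doubles the ratio
  q2 <- q; q2$conc[1:2, ] <- q2$conc[1:2, ] * 2
  expect_equal(as.numeric(pcpe_ratio(q2)), c(8, 8))
})

test_that("the DHA:ARA ratio uses anchored species sums per class", {
  feats <- data.frame(feature_id = paste0("f", 1:5),
                      name = c("PC 16:0_22:6", "PC 16:0_20:4", "PE 18:0_22:6",
                               "PE 18:0_20:4", "PC 40:6"),
                      msi_level = 2L)
  ann <- parse_lipid_annotations(feats)
  conc <- matrix(c(4, 2, 3, 1, 9), 5, 3,
                 dimnames = list(feats$name, paste0("A", 1:3)))
  q <- structure(list(conc = conc,
                      features = data.frame(name = feats$name,
                                            lipid_class = ann$lipid_class),
                      provenance = conc * 0, tissue = "liver",
                      esi_mode = "combined", units = "ug/mg"),
                 class = "quant_table")
  rownames(q$conc) <- ann$feature_id
  ratios <- dha_ara_ratio(q, ann)
  expect_equal(unname(ratios$PC), rep(2, 3))   # 4/2, sum-level PC excluded
  expect_equal(unname(ratios$PE), rep(3, 3))
  expect_identical(attr(ratios, "skipped"), "f5")
})

test_that("standard-curve calibration enforces linearity and floors negatives", {
  std <- data.frame(conc = c(1, 2, 4, 8), area = c(10, 20, 40, 80))
  out <- calibrate_targeted(std, unknowns = c(30, 5, -20))
  expect_true(out$calibrated)
  expect_equal(out$r_squared, 1)
  expect_equal(out$conc[1], 3)
  expect_equal(out$conc[3], 0)
  expect_identical(out$floored, 3L)
  # balanced design: mean area back-calculates to the mean concentration
  expect_equal(calibrate_targeted(std, mean(std$area))$conc[1], mean(std$conc))
  # pure-noise standards are rejected
  set.seed(5)
  bad <- data.frame(conc = 1:8, area = rnorm(8))
  expect_false(calibrate_targeted(bad, 1)$calibrated)
})
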