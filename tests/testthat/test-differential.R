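# Moderated linear models: OLS fits, variance prior, moderated t/F,
# sex contrasts, BH adjustment.

ols_fixture <- function(n_lipids = 40, seed = 11, groups = training_groups(),
                        n = 5) {
  set.seed(seed)
  meta <- data.frame(group = rep(groups, each = n))
  x <- matrix(rnorm(n_lipids * nrow(meta)), n_lipids,
              dimnames = list(sprintf("L%03d", seq_len(n_lipids)), NULL))
  list(x = x, meta = meta, X = design_matrix(meta, "means", groups))
}

test_that("means-model coefficients are the cell means and match the normal equations", {
  fx <- ols_fixture()
  fit <- fit_linear_models(fx$x, fx$X)
  means <- t(apply(fx$x, 1, function(v) tapply(v, fx$meta$group, mean)))
  expect_equal(unname(fit$coef), unname(means[, colnames(fit$coef)]),
               tolerance = 1e-12)
  # closed-form normal equations oracle
  beta <- t(solve(crossprod(fx$X)) %*% t(fx$X) %*% t(fx$x))
  expect_equal(unname(fit$coef), unname(beta), tolerance = 1e-12)
  expect_true(all(fit$df == ncol(fx$x) - ncol(fx$X)))
  # zero-noise data: s2 = 0
  x0 <- matrix(rep(1:5, each = 5), 2, 25, byrow = TRUE)
  fit0 <- fit_linear_models(x0, fx$X)
  expect_equal(unname(fit0$s2), c(0, 0), tolerance = 1e-25)
})

test_that("a rank-deficient design is rejected naming the aliased columns", {
  meta <- data.frame(group = rep(c("SED", "1w"), each = 5))
  X <- design_matrix(meta, "means", groups = c("SED", "1w"))
  X <- cbind(X, dup = X[, 1])
  expect_error(fit_linear_models(matrix(rnorm(30), 3), X), "dup")
})

test_that("the variance prior is recovered from scaled chi-square draws", {
  # s2 ~ s02 * d0 * chi2_df / (chi2_d0 * df) marginally; method of moments
  # on log s2 should recover d0 within 15% and s02 within 10%
  set.seed(31)
  d0 <- 4; s02 <- 0.25; df <- 8
  est <- replicate(10, {
    sigma2 <- s02 * d0 / rchisq(2000, d0)
    s2 <- sigma2 * rchisq(2000, df) / df
    pr <- estimate_prior(s2, df)
    c(pr$d0, pr$s02)
  })
  expect_lt(abs(median(est[1, ]) - d0) / d0, 0.15)
  expect_lt(abs(median(est[2, ]) - s02) / s02, 0.10)
})

test_that("prior limits: identical variances give infinite d0, spread gives small d0", {
  pr <- estimate_prior(rep(0.5, 50), df = 8)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s02, 0.5, tolerance = 1e-6)
  set.seed(8)
  s2_wild <- exp(rnorm(2000, 0, 3)) * rchisq(2000, 8) / 8
  expect_lt(estimate_prior(s2_wild, 8)$d0, 8)
})

test_that("moderated t with d0 = 0 is exactly the classical OLS t", {
  fx <- ols_fixture(seed = 5)
  fit <- fit_linear_models(fx$x, fx$X)
  cv <- c(SED = -1, `1w` = 1, `2w` = 0, `4w` = 0, `8w` = 0)[colnames(fx$X)]
  none <- structure(list(d0 = 0, s02 = 1), class = "moderation_prior")
  tt <- moderated_t(fit, cv, none)
  classical <- apply(fx$x, 1, function(v) {
    a <- v[fx$meta$group == "1w"]; b <- v[fx$meta$group == "SED"]
    res <- v - ave(v, fx$meta$group)
    s2 <- sum(res^2) / (length(v) - 5)
    (mean(a) - mean(b)) / sqrt(s2 * 2 / 5)
  })
  expect_equal(tt$t, unname(classical), tolerance = 1e-10)
  # d0 = Inf pools fully: the statistic uses s02 alone
  inf_pr <- structure(list(d0 = Inf, s02 = 2), class = "moderation_prior")
  ti <- moderated_t(fit, cv, inf_pr)
  expect_equal(ti$t, tt$logFC / sqrt(2 * 2 / 5), tolerance = 1e-10)
})

test_that("moderated statistics agree with the limma implementation", {
  skip_if_not_installed("limma")
  fx <- ols_fixture(n_lipids = 120, seed = 9)
  lf <- limma::lmFit(fx$x, fx$X)
  contr <- matrix(0, 5, 4, dimnames = list(colnames(fx$X),
                                           paste0(c("1w", "2w", "4w", "8w"), "_vs_SED")))
  contr["SED", ] <- -1
  contr[cbind(match(c("1w", "2w", "4w", "8w"), rownames(contr)), 1:4)] <- 1
  cf <- limma::eBayes(limma::contrasts.fit(lf, contr))
  fit <- fit_linear_models(fx$x, fx$X)
  pr <- estimate_prior(fit$s2, fit$df)
  expect_equal(pr$d0, cf$df.prior, tolerance = 1e-6)
  expect_equal(pr$s02, cf$s2.prior, tolerance = 1e-6)
  cv <- c(SED = -1, `1w` = 0, `2w` = 1, `4w` = 0, `8w` = 0)[colnames(fx$X)]
  tt <- moderated_t(fit, cv, pr)
  expect_equal(tt$t, unname(cf$t[, 2]), tolerance = 1e-8)
  expect_equal(tt$p, unname(cf$p.value[, 2]), tolerance = 1e-8)
  # moderated F over the four timewise contrasts
  ff <- moderated_F(fit, contr, pr)
  expect_equal(ff$F, unname(cf$F), tolerance = 1e-8)
  expect_equal(ff$p, unname(cf$F.p.value), tolerance = 1e-8)
})

test_that("a single-contrast moderated F equals the squared moderated t", {
  fx <- ols_fixture(seed = 13)
  fit <- fit_linear_models(fx$x, fx$X)
  pr <- estimate_prior(fit$s2, fit$df)
  cv <- c(SED = -1, `1w` = 0, `2w` = 0, `4w` = 1, `8w` = 0)[colnames(fx$X)]
  tt <- moderated_t(fit, cv, pr)
  ff <- moderated_F(fit, matrix(cv, ncol = 1), pr)
  expect_equal(ff$F, tt$t^2, tolerance = 1e-10)
  expect_equal(ff$p, tt$p, tolerance = 1e-10)
  expect_error(moderated_F(fit, cbind(cv, cv), pr), "dependent")
})

test_that("null moderated p-values are uniform", {
  fx <- ols_fixture(n_lipids = 600, seed = 17)
  r <- run_timewise(fx$x, fx$meta)
  p <- r$p[r$contrast != "F_overall"]
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
  expect_gt(stats::ks.test(p, "punif")$p.value, 1e-3)
  pf <- r$p[r$contrast == "F_overall"]
  expect_lt(abs(mean(pf < 0.05) - 0.05), 0.02)
})

test_that("sex contrasts separate naive differences from dimorphic responses", {
  set.seed(23)
  des <- study_design(tissues = "liver")
  meta <- des$animals
  mu <- ifelse(meta$sex == "male" & meta$group == "8w", 3, 0)  # male-only 8w
  base <- ifelse(meta$sex == "male", 1, 0)                      # sex baseline
  x <- rbind(dimorphic = mu + rnorm(50, 0, 0.2),
             baseline = base + rnorm(50, 0, 0.2),
             shared = ifelse(meta$group == "8w", 2, 0) + rnorm(50, 0, 0.2),
             matrix(rnorm(12 * 50, 0, 0.2), 12, 50,
                    dimnames = list(sprintf("null%02d", 1:12), NULL)))
  r <- sex_contrasts(x, meta)
  dim8 <- r[r$contrast == "dimorphic_8w", ]
  expect_gt(dim8$logFC[dim8$name == "dimorphic"], 2.5)
  expect_lt(dim8$adj_p[dim8$name == "dimorphic"], 0.01)
  # equal training response in both sexes cancels in the interaction
  expect_lt(abs(dim8$logFC[dim8$name == "shared"]), 0.5)
  expect_gt(dim8$p[dim8$name == "shared"], 0.01)
  # a pure sex baseline shows in the naive contrast, not the interaction
  nv <- r[r$contrast == "male_vs_female_SED", ]
  expect_gt(nv$logFC[nv$name == "baseline"], 0.5)
  expect_lt(abs(dim8$logFC[dim8$name == "baseline"]), 0.5)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.9)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_true(all(bh_adjust(p) >= p))
  # monotone in the raw p within a contrast
  expect_true(all(diff(bh_adjust(sort(runif(50)))) >= 0))
})
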