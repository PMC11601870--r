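# Cross-tissue correlation networks, signed TOM, module detection,
# module-phenotype correlations.


test_that("a duplicated lipid across tissues yields the top inter-tissue edge", {
  set.seed(2)
  a <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(paste0("L", 1:8), paste0("A", 1:10)))
  b <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(paste0("L", 1:8), paste0("A", 1:10)))
  b["L1", ] <- a["L1", ]  # identical profile in both tissues
  net <- build_correlation_network(list(liver = a, heart = b))
  e <- net$edges
  hit <- e[e$node_a == "liver|L1" & e$node_b == "heart|L1" |
           e$node_a == "heart|L1" & e$node_b == "liver|L1", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$r, 1)
  expect_identical(hit$scope, "inter")
  # graph structure: symmetric by construction, no self loops
  expect_false(any(e$node_a == e$node_b))
  expect_equal(net$n_tested, choose(16, 2) - net$n_skipped)
})

test_that("Bonferroni keeps null false edges below one in expectation", {
  false_edges <- vapply(1:20, function(s) {
    set.seed(100 + s)
    m <- matrix(rnorm(100 * 20), 100, 20,
                dimnames = list(sprintf("L%03d", 1:100), sprintf("A%02d", 1:20)))
    nrow(build_correlation_network(list(t1 = m))$edges)
  }, 0)
  expect_lt(mean(false_edges), 1)
})

test_that("TOM is 1 for identical profiles and bounded in [0, 1]", {
  # TOM_ij reaches 1 when a_ij = 1 and the shared-neighbour weights are
  # extremal, i.e. in a fully concordant background
  set.seed(3)
  latent <- rnorm(15)
  x_unit <- t(sapply(1:6, function(i) latent * runif(1, 0.5, 2)))
  rownames(x_unit) <- paste0("U", 1:6)
  tom_unit <- tom_similarity(x_unit, beta = 6)
  expect_true(all(abs(tom_unit - 1) < 1e-12))
  # a duplicated pair in a generic background: maximal adjacency, TOM high
  x <- matrix(rnorm(20 * 15), 20, 15, dimnames = list(paste0("L", 1:20), NULL))
  x[2, ] <- x[1, ]
  tom <- tom_similarity(x, beta = 6)
  expect_equal(max(tom[1, -1]), tom[1, 2])
  expect_true(all(diag(tom) == 1))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  # property sweep over random data
  for (s in 1:5) {
    set.seed(s)
    y <- matrix(rnorm(30 * 12), 30, 12, dimnames = list(paste0("M", 1:30), NULL))
    tt <- tom_similarity(y)
    expect_true(all(tt >= -1e-12 & tt <= 1 + 1e-12))
    expect_equal(tt, t(tt), tolerance = 1e-12)
  }
})

test_that("a 3-node TOM matches hand evaluation of the formula", {
  # fix correlations by constructing exact profiles is fiddly; instead
  # evaluate the formula directly from the realized correlation matrix
  set.seed(4)
  x <- matrix(rnorm(3 * 50), 3, 50, dimnames = list(c("a", "b", "c"), NULL))
  r <- cor(t(x))
  a <- ((1 + r) / 2)^6
  diag(a) <- 0
  k <- rowSums(a)
  expected_ab <- (sum(a["a", ] * a["b", ]) - a["a", "a"] * a["b", "a"] -
                  a["a", "b"] * a["b", "b"] + a["a", "b"]) /
                 (min(k["a"], k["b"]) + 1 - a["a", "b"])
  # with diag(a)=0 the cross terms above vanish; keep the plain form too
  expected_ab2 <- (a["a", "c"] * a["c", "b"] + a["a", "b"]) /
                  (min(k["a"], k["b"]) + 1 - a["a", "b"])
  tom <- tom_similarity(x, beta = 6)
  expect_equal(unname(tom["a", "b"]), unname(expected_ab2), tolerance = 1e-12)
  expect_equal(unname(expected_ab), unname(expected_ab2), tolerance = 1e-12)
})

test_that("module detection recovers planted blocks exactly and merges duplicates", {
  x <- block_data(n_block = 30, seed = 5)
  tom <- tom_similarity(x, beta = 6)
  ms <- detect_modules(tom, x, min_size = 10)
  found <- ms$labels[rownames(x)]
  truth <- rep(c("b1", "b2"), each = 30)
  expect_equal(adjusted_rand(found, truth), 1)
  expect_identical(length(ms$modules) - 1L, 2L)  # two modules + grey pool
  # near-duplicate modules (eigenprofile correlation > 0.85) merge
  x2 <- block_data(n_block = 20, seed = 6)
  half <- x2[1:20, ]
  dup <- half + matrix(rnorm(length(half), 0, 0.05), nrow(half))
  rownames(dup) <- paste0("D", seq_len(nrow(dup)))
  both <- rbind(half, dup)
  ms2 <- detect_modules(tom_similarity(both, beta = 6), both, min_size = 5)
  expect_identical(length(ms2$modules) - 1L, 1L)
})

test_that("eigenprofiles align with a rank-1 module's latent profile", {
  set.seed(7)
  latent <- rnorm(25)
  x <- t(sapply(1:15, function(i) runif(1, 0.5, 2) * latent))
  rownames(x) <- paste0("L", 1:15)
  colnames(x) <- paste0("A", 1:25)
  e <- lipidcourse:::.eigenprofile(x, rownames(x))
  expect_gt(abs(cor(e, latent)), 0.999)
  expect_gt(cor(e, colMeans(t(scale(t(x))))), 0)  # positive orientation
  expect_equal(sum(e^2), 1)                    # unit norm
})

test_that("membership scores flag hubs at the closed 0.7 threshold", {
  x <- block_data(n_block = 25, seed = 8, n_noise = 10)
  ms <- detect_modules(tom_similarity(x, beta = 6), x, min_size = 10)
  sc <- membership_scores(ms, x)
  for (mod in setdiff(names(ms$modules), "grey")) {
    members <- ms$modules[[mod]]
    expect_true(all(abs(sc$kme[sc$hubs[[mod]], mod]) >= 0.7))
    non_hub <- setdiff(members, sc$hubs[[mod]])
    if (length(non_hub))
      expect_true(all(abs(sc$kme[non_hub, mod]) < 0.7))
  }
  # a lipid orthogonal to the module has near-zero membership
  noise_kme <- sc$kme[sprintf("L%03d", 51:60), ]
  expect_lt(max(abs(noise_kme)), 0.5)
})

test_that("module-phenotype correlations recover planted links at rate alpha", {
  x <- block_data(n_block = 25, seed = 9)
  ms <- detect_modules(tom_similarity(x, beta = 6), x, min_size = 10)
  eig <- ms$eigenprofiles
  ph <- data.frame(animal_id = rownames(eig),
                   linked = eig[, 1] * 2 + rnorm(nrow(eig), 0, 0.05),
                   constant = 1,
                   noise = rnorm(nrow(eig)))
  out <- module_phenotype_correlation(ms, ph)
  linked <- out$correlations[out$correlations$phenotype == "linked" &
                             out$correlations$module == "M1", ]
  expect_gt(linked$r, 0.95)
  expect_true(linked$significant)
  expect_identical(out$skipped, "constant")
  # an exact eigenprofile copy correlates at 1
  ph$copy <- eig[, 2]
  out2 <- module_phenotype_correlation(ms, ph)
  copy <- out2$correlations[out2$correlations$phenotype == "copy" &
                            out2$correlations$module == "M2", ]
  expect_equal(copy$r, 1, tolerance = 1e-10)
})
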