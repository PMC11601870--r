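# Shared fixtures and small independent oracles, built in code at test time.

# Minimal feature_table constructor for hand-built fixtures.
make_feature_table <- function(areas, roles, orders = seq_along(roles),
                               animal_id = NULL, sex = NULL, group = NULL,
                               names = paste0("lip", seq_len(nrow(areas))),
                               msi_level = 2L, is_istd = FALSE,
                               lipid_class = NA_character_,
                               tissue = "liver", esi_mode = "positive") {
  n <- nrow(areas)
  features <- data.frame(
    name = names, lipid_class = rep_len(lipid_class, n),
    esi_mode = esi_mode, msi_level = rep_len(msi_level, n),
    is_istd = rep_len(is_istd, n),
    feature_id = sprintf("%s_%s_%04d", tissue, substr(esi_mode, 1, 3), seq_len(n)),
    stringsAsFactors = FALSE)
  if (is.null(animal_id))
    animal_id <- ifelse(roles == "study", paste0("A", cumsum(roles == "study")), NA)
  inj <- data.frame(
    injection_id = sprintf("inj%03d", seq_along(roles)), order = orders,
    role = roles, animal_id = animal_id,
    sex = if (is.null(sex)) NA_character_ else sex,
    group = if (is.null(group)) NA_character_ else group,
    stringsAsFactors = FALSE)
  dimnames(areas) <- list(features$feature_id, inj$injection_id)
  structure(list(areas = areas, features = features, injections = inj,
                 tissue = tissue, esi_mode = esi_mode, flags = list()),
            class = "feature_table")
}

# Brute-force GSEA-style running sum, written directly from the definition
# (walk the full ranked list, independent of the package's closed form).
brute_force_es <- function(metric, set, score_type = "std") {
  ids <- names(metric)
  ord <- order(-metric, ids)
  ranked <- metric[ord]
  hit <- names(ranked) %in% set
  w <- abs(ranked)
  if (sum(w[hit]) == 0) w[] <- 1
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (length(ranked) - sum(hit)))
  run <- cumsum(inc)
  if (score_type == "pos") return(max(run))
  if (max(run) >= abs(min(run))) max(run) else min(run)
}

# Exact one-sided Fisher p by enumeration over all tables with fixed margins.
enumerate_fisher_p <- function(overlap, n_query, n_set, n_bg) {
  ks <- max(0, n_query + n_set - n_bg):min(n_query, n_set)
  probs <- vapply(ks, function(k)
    choose(n_set, k) * choose(n_bg - n_set, n_query - k) / choose(n_bg, n_query), 0)
  sum(probs[ks >= overlap])
}

# Adjusted Rand index (standard contingency-table formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Small two-tissue design used by several pipeline-level tests.
small_design <- function(tissues = c("liver", "heart"))
  study_design(tissues = tissues)

# The power-evaluation effect panel: standardized size 3.0 at every
# timepoint, direction-balanced within each ESI mode, on classes outside the
# generator's latent co-expression blocks.
power_effects <- function(size = 3) {
  sz <- stats::setNames(rep(size, 4), c("1w", "2w", "4w", "8w"))
  list(effect_spec("timewise", classes = c("Car", "Cer"), size = sz),
       effect_spec("timewise", classes = c("LPC", "FFA"), size = -sz))
}

# Planted-structure fixtures shared across clustering/network tests.
archetype_data <- function(n_per = 30, noise = 0.1, seed = 1) {
  set.seed(seed)
  shapes <- rbind(c(0, 2, 2, 1, 0), c(0, -2, -2, -1, 0), c(0, 0.5, 1, 1.5, 2))
  x <- shapes[rep(1:3, each = n_per), ] + matrix(rnorm(3 * n_per * 5, 0, noise),
                                                 3 * n_per)
  rownames(x) <- sprintf("L%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(1:3, each = n_per))
}

block_data <- function(n_block = 30, n_samp = 40, load = 0.95, seed = 1,
                       n_noise = 0) {
  set.seed(seed)
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  x <- rbind(
    t(sapply(seq_len(n_block), function(i)
      load * f1 + rnorm(n_samp, 0, sqrt(1 - load^2)))),
    t(sapply(seq_len(n_block), function(i)
      load * f2 + rnorm(n_samp, 0, sqrt(1 - load^2)))))
  if (n_noise > 0) x <- rbind(x, matrix(rnorm(n_noise * n_samp), n_noise))
  rownames(x) <- sprintf("L%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("A%02d", seq_len(n_samp))
  x
}
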