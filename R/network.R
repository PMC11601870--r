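# Sample-level lipid correlation networks (inter/intra-tissue) and
# WGCNA-style signed-TOM co-expression modules with eigenprofiles, hub
# lipids, and phenotype correlations.

#' Cross-tissue sample-level correlation network
#'
#' Correlates every pair of (tissue, lipid) profiles over animals matched by
#' id within one sex, tests each Pearson r two-sided, Bonferroni-adjusts
#' over all tested pairs, and keeps edges with adjusted p below `alpha`.
#' Edges within a tissue are `"intra"`, between tissues `"inter"`. Pairs
#' with fewer than `min_samples` complete observations are skipped and
#' counted.
#'
#' @param matrices Named list (tissue) of lipids x animals matrices
#'   (normalized sample-level data of one sex).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_samples Minimal complete pairs per correlation (default 4).
#' @return A `network_graph`: list with `nodes` (tissue, name, node id,
#'   degree), `edges` (node_a, node_b, r, p, adj_p, sign, scope),
#'   `n_tested`, `n_skipped`, `tissue_pair_counts` (by sign).
#' @export
build_correlation_network <- function(matrices, alpha = 0.05, min_samples = 4L) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  animals <- Reduce(intersect, lapply(matrices, colnames))
  stopifnot(length(animals) >= min_samples)
  blocks <- lapply(names(matrices), function(tis) {
    m <- matrices[[tis]][, animals, drop = FALSE]
    rownames(m) <- paste(tis, rownames(m), sep = "|")
    m
  })
  big <- do.call(rbind, blocks)
  tissue_of <- sub("\\|.*$", "", rownames(big))
  r <- stats::cor(t(big), use = "pairwise.complete.obs")
  obs <- is.finite(big)
  n_pair <- tcrossprod(obs * 1)
  ut <- upper.tri(r)
  testable <- ut & n_pair >= min_samples & is.finite(r)
  n_tested <- sum(testable)
  n_skipped <- sum(ut & !testable)
  idx <- which(testable)
  rv <- r[idx]; nv <- n_pair[idx]
  rv_c <- pmin(pmax(rv, -1 + 1e-15), 1 - 1e-15)
  tstat <- rv_c * sqrt((nv - 2) / (1 - rv_c^2))
  p <- 2 * stats::pt(-abs(tstat), nv - 2)
  adj_p <- pmin(1, p * n_tested)  # Bonferroni over all tested pairs
  keep <- adj_p < alpha
  ai <- ((idx[keep] - 1L) %% nrow(r)) + 1L
  bi <- ((idx[keep] - 1L) %/% nrow(r)) + 1L
  edges <- data.frame(node_a = rownames(r)[ai], node_b = rownames(r)[bi],
                      r = rv[keep], p = p[keep], adj_p = adj_p[keep],
                      sign = ifelse(rv[keep] >= 0, "positive", "negative"),
                      scope = ifelse(tissue_of[ai] == tissue_of[bi],
                                     "intra", "inter"),
                      stringsAsFactors = FALSE)
  deg <- table(factor(c(edges$node_a, edges$node_b), levels = rownames(r)))
  nodes <- data.frame(node = rownames(r), tissue = tissue_of,
                      name = sub("^[^|]*\\|", "", rownames(r)),
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  inter <- edges[edges$scope == "inter", , drop = FALSE]
  tp <- if (nrow(inter)) {
    pair <- t(apply(cbind(sub("\\|.*$", "", inter$node_a),
                          sub("\\|.*$", "", inter$node_b)), 1L, sort))
    stats::aggregate(rep(1L, nrow(inter)),
                     by = list(tissue_a = pair[, 1], tissue_b = pair[, 2],
                               sign = inter$sign), FUN = sum)
  } else NULL
  if (!is.null(tp)) names(tp)[4] <- "n_edges"
  structure(list(nodes = nodes, edges = edges, n_tested = n_tested,
                 n_skipped = n_skipped, tissue_pair_counts = tp,
                 alpha = alpha),
            class = "network_graph")
}

#' Export a network as edge-list and node TSVs
#' @param graph A `network_graph`.
#' @param edge_path,node_path Output files.
#' @export
write_network <- function(graph, edge_path, node_path) {
  utils::write.table(graph$edges, edge_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(graph$nodes, node_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(edge_path)
}

#' Signed topological overlap matrix
#'
#' Soft-thresholds the signed correlation adjacency
#' `a_ij = ((1 + r_ij)/2)^beta` and computes the topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the adjacency row sums (diagonal excluded); the diagonal is set to 1.
#'
#' @param values Lipids x samples matrix.
#' @param beta Soft-threshold power (default 6).
#' @param signed Signed adjacency (default TRUE; unsigned uses `|r|^beta`).
#' @return Symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(values, beta = 6L, signed = TRUE) {
  stopifnot(beta >= 1)
  r <- stats::cor(t(values), use = "pairwise.complete.obs")
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(r)
  tom
}

# First principal component of the standardized module submatrix, unit norm,
# sign-oriented to correlate positively with the module mean profile.
.eigenprofile <- function(values, members) {
  sub <- values[members, , drop = FALSE]
  z <- t(scale(t(sub)))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  mean_prof <- colMeans(z)
  if (stats::cor(e, mean_prof) < 0) e <- -e
  stats::setNames(e, colnames(values))
}

.modularity <- function(w, labels) {
  # weighted Newman modularity; unassigned nodes (label 0) count as
  # singleton communities so a large grey pool is penalized, not rewarded
  diag(w) <- 0
  tot <- sum(w)
  if (tot == 0) return(0)
  q <- 0
  for (l in setdiff(unique(labels), 0)) {
    in_l <- labels == l
    q <- q + sum(w[in_l, in_l]) / tot - (sum(w[in_l, ]) / tot)^2
  }
  for (i in which(labels == 0))
    q <- q - (sum(w[i, ]) / tot)^2
  q
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' (1 - TOM), with the tree cut at the height (over a candidate grid of
#' merge heights) that maximizes weighted modularity of the TOM graph.
#' Modules smaller than `min_size` fall into the grey pool; modules whose
#' eigenprofiles correlate above `1 - merge_cut` are merged iteratively.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param values The lipids x samples matrix behind the TOM (for
#'   eigenprofiles).
#' @param min_size Minimal module size (default 10).
#' @param merge_cut Eigenprofile merge height (default 0.15, i.e. merge at
#'   correlation > 0.85).
#' @return A `module_set`: list with `modules` (named list of lipid ids;
#'   `grey` holds the unassigned pool), `labels`, `eigenprofiles` (samples x
#'   modules, unit norm), `kme` (lipids x modules), `hubs` (per module,
#'   members with |kME| >= 0.7), `beta` attribute of the call.
#' @export
detect_modules <- function(tom, values, min_size = 10L, merge_cut = 0.15) {
  stopifnot(min_size >= 3L, all(rownames(tom) %in% rownames(values)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # candidate cuts: midpoints between consecutive merge heights (every
  # distinct dendrogram partition), thinned to at most 40 but always keeping
  # the cuts just below the top merges
  hs <- sort(unique(hc$height))
  mids <- if (length(hs) > 1L) (hs[-1] + hs[-length(hs)]) / 2 else hs
  if (length(mids) > 40L)
    mids <- sort(unique(c(mids[round(seq(1, length(mids), length.out = 35))],
                          utils::tail(mids, 5))))
  best <- NULL
  for (h in mids) {
    lab <- stats::cutree(hc, h = h)
    sizes <- table(lab)
    lab[lab %in% names(sizes)[sizes < min_size]] <- 0L
    if (length(unique(lab[lab != 0L])) < 1L) next
    q <- .modularity(tom, lab)
    if (is.null(best) || q > best$q) best <- list(q = q, lab = lab)
  }
  if (is.null(best)) {
    warning("all lipids grey: no module of the required size")
    return(structure(list(modules = list(grey = rownames(tom)),
                          labels = stats::setNames(rep("grey", nrow(tom)), rownames(tom)),
                          eigenprofiles = NULL, kme = NULL, hubs = list()),
                     class = "module_set"))
  }
  lab <- best$lab
  # iterative eigenprofile merge
  repeat {
    mods <- split(rownames(tom), lab)
    mods <- mods[names(mods) != "0"]
    if (length(mods) < 2L) break
    eig <- vapply(mods, function(ids) .eigenprofile(values, ids),
                  numeric(ncol(values)))
    ec <- stats::cor(eig)
    diag(ec) <- -Inf
    top <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (max(ec) <= 1 - merge_cut) break
    lab[lab == as.integer(names(mods)[top[2]])] <- as.integer(names(mods)[top[1]])
  }
  mods <- split(rownames(tom), lab)
  grey <- mods[["0"]]
  mods <- mods[names(mods) != "0"]
  mods <- mods[order(-lengths(mods))]
  names(mods) <- paste0("M", seq_along(mods))
  eig <- vapply(mods, function(ids) .eigenprofile(values, ids),
                numeric(ncol(values)))
  rownames(eig) <- colnames(values)
  kme <- stats::cor(t(values), eig, use = "pairwise.complete.obs")
  labels <- stats::setNames(rep("grey", nrow(tom)), rownames(tom))
  for (nm in names(mods)) labels[mods[[nm]]] <- nm
  hubs <- lapply(names(mods), function(nm)
    mods[[nm]][abs(kme[mods[[nm]], nm]) >= 0.7])
  names(hubs) <- names(mods)
  structure(list(modules = c(mods, list(grey = if (is.null(grey)) character() else grey)),
                 labels = labels, eigenprofiles = eig, kme = kme, hubs = hubs),
            class = "module_set")
}

#' Module membership (kME) scores
#'
#' Pearson correlation of each lipid profile with each module eigenprofile;
#' the hub flag uses the closed threshold |kME| >= `hub_min`.
#'
#' @param modules A `module_set`.
#' @param values Lipids x samples matrix.
#' @param hub_min Hub threshold (default 0.7).
#' @return List with `kme` matrix and `hubs` (per module).
#' @export
membership_scores <- function(modules, values, hub_min = 0.7) {
  stopifnot(inherits(modules, "module_set"), !is.null(modules$eigenprofiles))
  kme <- stats::cor(t(values), modules$eigenprofiles,
                    use = "pairwise.complete.obs")
  hubs <- lapply(colnames(kme), function(nm) {
    members <- modules$modules[[nm]]
    members[abs(kme[members, nm]) >= hub_min]
  })
  names(hubs) <- colnames(kme)
  list(kme = kme, hubs = hubs)
}

#' Module-phenotype correlations
#'
#' Pearson correlation of each module eigenprofile with each phenotype over
#' matched animals; edges are reported at raw p below `alpha` (the
#' figure-level convention). Constant phenotypes are skipped and flagged.
#'
#' @param modules A `module_set` (eigenprofiles over animal columns).
#' @param phenotypes data.frame with `animal_id` and numeric phenotype
#'   columns.
#' @param alpha Raw-p threshold (default 0.05).
#' @return List with `correlations` (module, phenotype, r, p, significant)
#'   and `skipped` phenotypes.
#' @export
module_phenotype_correlation <- function(modules, phenotypes, alpha = 0.05) {
  stopifnot(inherits(modules, "module_set"), !is.null(modules$eigenprofiles))
  eig <- modules$eigenprofiles
  ph <- phenotypes[match(rownames(eig), phenotypes$animal_id), , drop = FALSE]
  stopifnot(!anyNA(ph$animal_id))
  num_cols <- names(ph)[vapply(ph, is.numeric, FALSE)]
  rows <- list(); skipped <- character()
  for (pc in num_cols) {
    v <- ph[[pc]]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(!is.finite(v))) {
      skipped <- c(skipped, pc); next
    }
    for (mod in colnames(eig)) {
      ct <- stats::cor.test(eig[, mod], v)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, phenotype = pc, r = unname(ct$estimate), p = ct$p.value,
        significant = ct$p.value < alpha, stringsAsFactors = FALSE)
    }
  }
  list(correlations = do.call(rbind, rows), skipped = skipped)
}
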