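# Rank-based lipid-set enrichment (LSEA, GSEA-type weighted running sum)
# and one-sided Fisher over-representation analysis.

.rank_order <- function(metric) {
  # decreasing metric; ties broken deterministically by feature id
  ids <- names(metric)
  ord <- order(-metric, ids)
  metric[ord]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing by
#' `|metric|/sum(|metric| in set)` at set members (weight exponent 1) and
#' decrementing by `1/(n - set size)` elsewhere; the enrichment score is the
#' running-sum extremum (the positive extremum only under
#' `score_type = "pos"`, used when all metrics are nonnegative). Ties in the
#' metric are broken by feature id.
#'
#' @param metric Named numeric vector (feature id -> ranking metric, e.g.
#'   signed -log10 p or a nonnegative F-score).
#' @param set Character vector of member feature ids (subset of the universe).
#' @param score_type `"std"` (two-sided extremum) or `"pos"`.
#' @return List with `es`, `leading_edge` (feature ids), and `positions` of
#'   the set in the ranked list.
#' @export
enrichment_score <- function(metric, set, score_type = c("std", "pos")) {
  score_type <- match.arg(score_type)
  if (!length(set)) stop("empty lipid set")
  stopifnot(!is.null(names(metric)), all(set %in% names(metric)))
  ranked <- .rank_order(metric)
  n <- length(ranked); s <- length(set)
  pos <- sort(match(set, names(ranked)))
  w <- abs(ranked[pos])
  if (sum(w) == 0) w <- rep(1, s)  # all-zero metrics degrade to unweighted
  cw <- cumsum(w) / sum(w)
  miss <- if (n > s) 1 / (n - s) else 0
  at_hit <- cw - (pos - seq_len(s)) * miss
  before_hit <- c(0, cw[-s]) - (pos - seq_len(s)) * miss
  es_pos <- max(at_hit)
  es_neg <- min(before_hit)
  es <- if (score_type == "pos" || es_pos >= abs(es_neg)) es_pos else es_neg
  le <- if (es >= 0) names(ranked)[pos[seq_len(which.max(at_hit))]]
        else names(ranked)[pos[seq(which.min(before_hit), s)]]
  list(es = unname(es), leading_edge = le, positions = pos)
}

#' Lipid-set enrichment analysis (LSEA)
#'
#' Scores each eligible set against the ranked list and estimates
#' significance from a permutation null of random same-size feature sets:
#' `p = (1 + #{null |ES| at least as extreme}) / (1 + n_perm)` (magnitudes,
#' matching the two-sided extremum statistic). The normalized enrichment
#' score is the observed ES divided by the mean absolute null ES of matching
#' sign. BH adjustment is applied across sets.
#'
#' @param metric Named ranking metric vector over the universe.
#' @param catalog A `lipid_set_catalog` ([build_class_sets()]) or named list
#'   of feature-id vectors.
#' @param n_perm Permutations (default 10000).
#' @param min_size Minimal set size (default 10).
#' @param score_type See [enrichment_score()]; `"pos"` restricts to the
#'   positive extremum for nonnegative metrics such as F-scores.
#' @param seed Integer seed for the permutation null.
#' @return data.frame per set: `set`, `size`, `es`, `nes`, `p`, `adj_p`,
#'   `leading_edge` (comma-joined ids).
#' @export
lsea <- function(metric, catalog, n_perm = 10000L, min_size = 10L,
                 score_type = c("std", "pos"), seed = 1L) {
  score_type <- match.arg(score_type)
  sets <- if (inherits(catalog, "lipid_set_catalog")) catalog$sets else catalog
  sets <- lapply(sets, intersect, y = names(metric))
  sets <- sets[lengths(sets) >= min_size]
  if (!length(sets)) stop("no eligible set (after the minimal-size filter)")
  sets <- sets[order(names(sets))]
  set.seed(as.integer(seed))
  ids <- names(metric)
  rows <- lapply(names(sets), function(nm) {
    obs <- enrichment_score(metric, sets[[nm]], score_type)
    s <- length(sets[[nm]])
    null_es <- vapply(seq_len(n_perm), function(i)
      enrichment_score(metric, sample(ids, s), score_type)$es, 0)
    extreme <- sum(abs(null_es) >= abs(obs$es))
    p <- (1 + extreme) / (1 + n_perm)
    same_sign <- null_es[sign(null_es) == sign(obs$es) & null_es != 0]
    denom <- if (length(same_sign)) mean(abs(same_sign)) else mean(abs(null_es))
    data.frame(set = nm, size = s, es = obs$es,
               nes = if (denom > 0) obs$es / denom else NA_real_, p = p,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out[, c("set", "size", "es", "nes", "p", "adj_p", "leading_edge")]
}

#' One-sided over-representation test
#'
#' Hypergeometric (one-sided Fisher) enrichment p-value for the overlap of a
#' query with a set inside a background universe.
#'
#' @param query,set,background Character vectors of feature ids; query and
#'   set must lie inside the background.
#' @return List with `p`, `overlap`, `expected`, and the 2x2 table counts.
#' @export
ora <- function(query, set, background) {
  if (!length(background)) stop("empty background")
  query <- unique(query); set <- unique(set); background <- unique(background)
  stopifnot(all(query %in% background), all(set %in% background))
  k <- length(intersect(query, set))
  p <- stats::phyper(k - 1, length(set), length(background) - length(set),
                     length(query), lower.tail = FALSE)
  list(p = p, overlap = k,
       expected = length(query) * length(set) / length(background),
       in_query = length(query), in_set = length(set),
       n_background = length(background))
}

#' Over-representation analysis across a set catalog
#'
#' Runs [ora()] for one query (e.g. a cluster core or module hub list)
#' against every catalog set of at least `min_size`, with BH adjustment.
#'
#' @inheritParams lsea
#' @param query Feature ids (e.g. core lipids with membership >= 0.5, or hub
#'   lipids with membership >= 0.7).
#' @param background All named lipids.
#' @return data.frame: `set`, `size`, `overlap`, `expected`, `p`, `adj_p`.
#' @export
ora_catalog <- function(query, catalog, background, min_size = 10L) {
  sets <- if (inherits(catalog, "lipid_set_catalog")) catalog$sets else catalog
  sets <- lapply(sets, intersect, y = background)
  sets <- sets[lengths(sets) >= min_size]
  if (!length(sets)) stop("no eligible set (after the minimal-size filter)")
  rows <- lapply(names(sets), function(nm) {
    r <- ora(intersect(query, background), sets[[nm]], background)
    data.frame(set = nm, size = r$in_set, overlap = r$overlap,
               expected = r$expected, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out
}
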