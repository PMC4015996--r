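## Competitive gene-set enrichment ranking of conditions, PCA views, and
## the deterministic heatmap layout.

#' Competitive gene-set test
#'
#' Wilcoxon rank-sum comparison of the per-gene statistics of a set against
#' all other genes (normal approximation without continuity correction, so
#' p-values depend only on ranks and are invariant to monotone transforms
#' of the statistics). `direction = "up"` asks whether the set ranks high,
#' `"down"` low, `"either"` is two-sided.
#'
#' @param stats named per-gene statistics (e.g. moderated t of a condition
#'   versus baseline).
#' @param set gene symbols; must intersect the universe.
#' @param direction "up", "down" or "either".
#' @return list with `statistic` (rank-sum W), `mean_rank` of the set, and
#'   `p`. A set spanning the whole universe has no competition: p = 1.
#' @export
gene_set_test <- function(stats, set, direction = c("up", "down", "either")) {
  direction <- match.arg(direction)
  in_set <- names(stats) %in% set
  if (!any(in_set)) stop("gene set does not intersect the universe")
  if (all(in_set)) {
    return(list(statistic = NA_real_, mean_rank = mean(rank(stats)), p = 1))
  }
  alt <- switch(direction, up = "greater", down = "less", either = "two.sided")
  wt <- wilcox.test(stats[in_set], stats[!in_set], alternative = alt,
                    exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic),
       mean_rank = mean(rank(stats)[in_set]),
       p = wt$p.value)
}

#' Condition-level enrichment table for the wanted/unwanted sets
#'
#' For every factorial condition except the baseline, computes moderated t
#' statistics versus the baseline and the competitive enrichment p of the
#' wanted and unwanted sets (upward enrichment), then BH-adjusts across
#' conditions within each set. A condition is flagged `enriched_wanted_only`
#' when its wanted FDR is below `fdr` and its unwanted FDR is not; the table
#' is sorted by wanted FDR (flagged conditions ranking by the same key).
#'
#' @param expr an `expression_screen`.
#' @param registry a `condition_registry`.
#' @param day assay day (default 7).
#' @param baseline_id baseline condition (default 32, the factor-free
#'   medium).
#' @param fdr FDR threshold for the flag.
#' @return a `gene_set_result` data.frame: `condition_id`, `wanted_p`,
#'   `wanted_fdr`, `unwanted_p`, `unwanted_fdr`, `enriched_wanted_only`.
#' @export
enrichment_table <- function(expr, registry, day = 7L, baseline_id = 32L,
                             fdr = 0.05) {
  ids <- registry$id[registry$arm == "factorial"]
  ids <- setdiff(intersect(ids, expr$design$condition_id[
    expr$design$day == day]), baseline_id)
  if (!baseline_id %in% expr$design$condition_id[expr$design$day == day]) {
    stop("baseline condition ", baseline_id, " absent at day ", day)
  }
  wanted <- panel_symbols(expr$panel, marker_set = "wanted")
  unwanted <- panel_symbols(expr$panel, marker_set = "unwanted")
  rows <- lapply(ids, function(cid) {
    de <- de_contrast(expr, cid, baseline_id, day = day)
    stats <- setNames(de$t_mod, de$symbol)
    data.frame(condition_id = cid,
               wanted_p = gene_set_test(stats, wanted, "up")$p,
               unwanted_p = gene_set_test(stats, unwanted, "up")$p)
  })
  out <- do.call(rbind, rows)
  out$wanted_fdr <- bh_adjust(out$wanted_p)
  out$unwanted_fdr <- bh_adjust(out$unwanted_p)
  out$enriched_wanted_only <- out$wanted_fdr < fdr & out$unwanted_fdr >= fdr
  out <- out[order(out$wanted_fdr, out$wanted_p, out$condition_id),
             c("condition_id", "wanted_p", "wanted_fdr", "unwanted_p",
               "unwanted_fdr", "enriched_wanted_only")]
  rownames(out) <- NULL
  class(out) <- c("gene_set_result", "data.frame")
  out
}

#' Principal component analysis of an expression screen
#'
#' Gene-centered SVD (via [stats::prcomp()]) of the selected samples, with a
#' fixed sign convention: for each component, the gene with the largest
#' absolute loading has a positive loading.
#'
#' @param expr an `expression_screen`.
#' @param day optional day filter; @param conditions optional condition
#'   filter.
#' @param center,scale. passed to `prcomp` (defaults: center, no scaling).
#' @return a `pca_result`: list with `scores` (samples x PCs, annotated
#'   with condition/donor/day), `loadings` (genes x PCs, orthonormal) and
#'   `var_explained` (fractions summing to 1).
#' @export
pca_screen <- function(expr, day = NULL, conditions = NULL, center = TRUE,
                       scale. = FALSE) {
  design <- expr$design
  keep <- rep(TRUE, nrow(design))
  if (!is.null(day)) keep <- keep & design$day %in% day
  if (!is.null(conditions)) keep <- keep & design$condition_id %in% conditions
  design <- design[keep, , drop = FALSE]
  mat <- t(expr$expr[, design$sample_id, drop = FALSE])
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("PCA needs >= 2 samples and genes")
  if (all(apply(mat, 2, sd) == 0)) stop("constant expression matrix")
  if (scale.) mat <- mat[, apply(mat, 2, sd) > 0, drop = FALSE]
  pc <- prcomp(mat, center = center, scale. = scale.)
  ## sign convention: dominant loading positive, per component
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = cbind(design,
                                as.data.frame(pc$x[, , drop = FALSE])),
                 loadings = pc$rotation,
                 var_explained = ve),
            class = "pca_result")
}

#' Deterministic heatmap layout for marker genes
#'
#' Rows: wanted markers then unwanted markers, each alphabetical; columns:
#' condition ids in wanted-score rank order (optionally only flagged
#' conditions).
#'
#' @param panel a `gene_panel`.
#' @param scores a `marker_score_table`.
#' @param conditions optional subset of condition ids to keep, in rank
#'   order.
#' @return list with `rows` (symbols) and `cols` (condition ids).
#' @export
heatmap_order <- function(panel, scores, conditions = NULL) {
  rows <- c(sort(panel_symbols(panel, marker_set = "wanted")),
            sort(panel_symbols(panel, marker_set = "unwanted")))
  ord <- scores$condition_id[order(scores$rank)]
  if (!is.null(conditions)) ord <- ord[ord %in% conditions]
  list(rows = rows, cols = ord)
}
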