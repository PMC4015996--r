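## Studentized marker scoring: condition-level z-profiles, wanted/unwanted
## summary scores, ranking and rank/profile correlations.

#' Studentize expression across conditions
#'
#' Replicate samples are first collapsed to condition means (one column per
#' condition), then each gene row is z-scored across conditions: subtract
#' the row mean and divide by the sample (n-1) standard deviation. Rows with
#' zero SD are set to all zeros and flagged as degenerate rather than NaN,
#' so marker-set means remain defined.
#'
#' @param expr an `expression_screen`.
#' @param day restrict to samples of this day (default: all samples).
#' @param conditions restrict to these condition ids (default: all present
#'   after the day filter).
#' @param collapse replicate handling; `"mean_over_replicates"` (the only
#'   built-in) averages donors per condition, `"none"` studentizes per
#'   sample column.
#' @return a `studentized_matrix`: list with `z` (genes x conditions),
#'   `day`, `center`/`scale` per gene (for audit) and `degenerate` flags.
#' @export
studentize <- function(expr, day = NULL, conditions = NULL,
                       collapse = c("mean_over_replicates", "none")) {
  collapse <- match.arg(collapse)
  design <- expr$design
  keep <- rep(TRUE, nrow(design))
  if (!is.null(day)) keep <- keep & design$day %in% day
  if (!is.null(conditions)) keep <- keep & design$condition_id %in% conditions
  design <- design[keep, , drop = FALSE]
  mat <- expr$expr[, design$sample_id, drop = FALSE]
  if (collapse == "mean_over_replicates") {
    conds <- sort(unique(design$condition_id))
    mat <- vapply(conds, function(cid) {
      rowMeans(mat[, design$condition_id == cid, drop = FALSE])
    }, numeric(nrow(mat)))
    colnames(mat) <- conds
  }
  if (ncol(mat) < 2) {
    stop("studentization needs at least 2 conditions")
  }
  ctr <- rowMeans(mat)
  scl <- apply(mat, 1, sd)
  degen <- scl == 0
  z <- (mat - ctr) / ifelse(degen, 1, scl)
  z[degen, ] <- 0
  structure(list(z = z, day = day, center = ctr, scale = scl,
                 degenerate = degen),
            class = "studentized_matrix")
}

#' Wanted/unwanted marker scores per condition
#'
#' The wanted (unwanted) score of a condition is the mean of the
#' studentized values of the wanted (unwanted) marker genes in that
#' condition. Conditions are ranked descending by wanted score, with ties
#' broken by ascending unwanted score, then by condition id.
#'
#' @param z a `studentized_matrix`.
#' @param panel the `gene_panel` defining the marker sets.
#' @return a `marker_score_table` data.frame: `condition_id`, `wanted`,
#'   `unwanted`, `rank`.
#' @export
marker_scores <- function(z, panel) {
  wanted <- panel_symbols(panel, marker_set = "wanted")
  unwanted <- panel_symbols(panel, marker_set = "unwanted")
  if (!all(wanted %in% rownames(z$z)) || !all(unwanted %in% rownames(z$z))) {
    stop("marker set gene(s) absent from the studentized matrix")
  }
  if (!length(wanted) || !length(unwanted)) stop("empty marker set")
  out <- data.frame(
    condition_id = as.integer(colnames(z$z)),
    wanted = colMeans(z$z[wanted, , drop = FALSE]),
    unwanted = colMeans(z$z[unwanted, , drop = FALSE])
  )
  ord <- order(-out$wanted, out$unwanted, out$condition_id)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("marker_score_table", "data.frame")
  out
}

#' Per-sample marker responses
#'
#' Mean normalized log2 expression of each marker set per sample — the
#' responses used for factorial effect inference (one observation per
#' condition and donor, unlike [marker_scores()] which collapses donors).
#'
#' @param expr an `expression_screen`.
#' @param registry optional `condition_registry` used to restrict to `arms`.
#' @param day restrict to this day.
#' @param arms restrict to design arms (default factorial) when `registry`
#'   is given.
#' @return data.frame `sample_id`, `condition_id`, `donor`, `day`,
#'   `wanted`, `unwanted`.
#' @export
marker_responses <- function(expr, registry = NULL, day = 7L,
                             arms = "factorial") {
  design <- expr$design
  keep <- design$day %in% day & design$condition_id != UNTREATED_ID
  if (!is.null(registry)) {
    ids <- registry$id[registry$arm %in% arms]
    keep <- keep & design$condition_id %in% ids
  }
  design <- design[keep, , drop = FALSE]
  wanted <- panel_symbols(expr$panel, marker_set = "wanted")
  unwanted <- panel_symbols(expr$panel, marker_set = "unwanted")
  data.frame(
    sample_id = design$sample_id,
    condition_id = design$condition_id,
    donor = design$donor,
    day = design$day,
    wanted = colMeans(expr$expr[wanted, design$sample_id, drop = FALSE]),
    unwanted = colMeans(expr$expr[unwanted, design$sample_id, drop = FALSE]),
    row.names = NULL
  )
}

#' Spearman correlation between two condition rankings
#'
#' Rank agreement of the wanted-score rankings of two marker score tables
#' (e.g. day 1 vs day 7), with average-rank ties; the p-value uses the t
#' approximation, or the exact permutation distribution for n <= 9.
#'
#' @param day1,day7 `marker_score_table`s over the same condition set.
#' @return list with `rho` and `p`.
#' @export
rank_correlation <- function(day1, day7) {
  if (!setequal(day1$condition_id, day7$condition_id)) {
    stop("marker score tables cover different condition sets")
  }
  x <- day1$wanted
  y <- day7$wanted[match(day1$condition_id, day7$condition_id)]
  n <- length(x)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n <= 9)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Pearson correlation between two expression profiles
#'
#' For paired log-scale profiles over the same gene universe (e.g. lysate
#' vs purified RNA of the same sample): Pearson r, the coefficient of
#' determination r^2, and the two-sided p-value.
#'
#' @param a,b numeric profiles of equal length >= 3.
#' @return list with `r`, `r2`, `p`.
#' @export
profile_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must share the gene universe")
  if (length(a) < 3) stop("need at least 3 genes")
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero variance in a profile: correlation undefined")
  }
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2, p = ct$p.value)
}
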