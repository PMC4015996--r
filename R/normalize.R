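## Normalization chain: spike-in lane scaling, NormFinder-style reference
## gene stability, geometric-mean reference normalization, generalized log.

## Geometric mean; zeros are an error unless a pseudo-count is configured,
## in which case it is added to every value of the affected computation.
geomean <- function(x, pseudo_count = NULL, what = "counts") {
  if (any(x == 0)) {
    if (is.null(pseudo_count)) {
      stop("zero ", what, " encountered: the geometric mean is undefined; ",
           "set a pseudo_count to proceed")
    }
    x <- x + pseudo_count
  }
  exp(mean(log(x)))
}

#' Lane-to-lane scale factors from positive spike-in controls
#'
#' For each sample, the factor equalizing positive-control geometric means:
#' `factor_s = geomean over samples of per-sample positive-control geomeans,
#' divided by the positive-control geomean of sample s`. Multiplying sample
#' `s` by `factor_s` gives every sample the same positive-control geometric
#' mean.
#'
#' @param screen a `count_screen` with at least one positive-control probe.
#' @param pseudo_count optional pseudo-count for zero counts (default: a
#'   zero positive-control count is an error).
#' @return named positive numeric, one factor per sample.
#' @export
lane_scale_factors <- function(screen, pseudo_count = NULL) {
  pos <- screen$counts[screen$panel$cls == "positive_ctrl", , drop = FALSE]
  if (nrow(pos) == 0) stop("no positive-control probes in the panel")
  gm <- apply(pos, 2, geomean, pseudo_count = pseudo_count,
              what = "positive-control count")
  setNames(exp(mean(log(gm))) / gm, colnames(screen$counts))
}

## Internal: a screen whose counts have been rescaled (no integer check).
scaled_screen <- function(screen, counts, extra = list()) {
  out <- screen
  out$counts <- counts
  out$provenance <- c(screen$provenance, extra)
  out
}

#' Apply lane scale factors to a screen
#'
#' @param screen a `count_screen`.
#' @param factors per-sample factors from [lane_scale_factors()].
#' @return the screen with scaled (no longer integer) counts; factors are
#'   recorded in `$provenance$lane_factors`.
#' @export
apply_lane_scaling <- function(screen, factors = lane_scale_factors(screen)) {
  counts <- sweep(screen$counts, 2, factors[colnames(screen$counts)], "*")
  scaled_screen(screen, counts, list(lane_factors = factors))
}

#' NormFinder-style stability of candidate reference genes
#'
#' Variance-decomposition stability model for reference-gene selection on
#' log-scale expression. Within each sample group, the intra-group variation
#' of candidate `i` is estimated from the residuals of the additive
#' gene + sample model, with the multi-candidate correction factor
#' `k/(k-1)`; the inter-group variation is the group-specific deviation of
#' the candidate's centered mean, shrunk toward zero by its sampling
#' variance. The combined stability is
#' `rho_i = mean over groups of (|d_ig| + sigma_ig)`; lower is more stable.
#'
#' @param expr log-scale matrix, candidate genes x samples (>= 3
#'   candidates).
#' @param groups sample group labels (>= 2 samples per group); with a single
#'   group the inter-group term vanishes and the ranking reduces to residual
#'   variance.
#' @return a `stability_table` data.frame: `symbol`, `intra_sd` (mean
#'   sigma_ig), `inter_d` (mean |shrunk d_ig|), `rho`, `rank`.
#' @export
normfinder_stability <- function(expr, groups) {
  k <- nrow(expr)
  if (k < 3) stop("need at least 3 candidate genes for stability ranking")
  groups <- as.character(groups)
  if (length(groups) != ncol(expr)) stop("groups must label every sample")
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("every group needs at least 2 samples; offending group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  glev <- names(tab)
  G <- length(glev)

  sigma <- matrix(NA_real_, k, G, dimnames = list(rownames(expr), glev))
  cmean <- matrix(NA_real_, k, G, dimnames = list(rownames(expr), glev))
  n_g <- setNames(as.integer(tab), glev)
  for (g in glev) {
    X <- expr[, groups == g, drop = FALSE]
    n <- ncol(X)
    r <- X - rowMeans(X) -
      rep(colMeans(X), each = k) + mean(X)
    v <- rowSums(r^2) / (n - 1) * k / (k - 1)
    sigma[, g] <- sqrt(pmax(v, 0))
    cmean[, g] <- rowMeans(X) - mean(X)
  }
  ## group deviation of the centered candidate means, shrunk by sampling var
  d <- cmean - rowMeans(cmean)
  d_shrunk <- d
  if (G > 1) {
    for (g in glev) {
      samp_var <- sigma[, g]^2 / n_g[g] * (G - 1) / G
      tau2 <- max(0, var(d[, g]) - mean(samp_var))
      shrink <- ifelse(tau2 + samp_var > 0, tau2 / (tau2 + samp_var), 0)
      d_shrunk[, g] <- d[, g] * shrink
    }
  } else {
    d_shrunk[] <- 0
  }
  rho <- rowMeans(abs(d_shrunk) + sigma)
  out <- data.frame(symbol = rownames(expr),
                    intra_sd = rowMeans(sigma),
                    inter_d = rowMeans(abs(d_shrunk)),
                    rho = rho,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rho, out$symbol), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Select reference genes from a stability table
#'
#' The `n_refs` candidates with lowest stability value; ties broken
#' lexicographically by symbol (deterministic).
#'
#' @param stability a `stability_table`.
#' @param n_refs number of references (default 5).
#' @return character vector of symbols.
#' @export
select_references <- function(stability, n_refs = 5L) {
  if (n_refs > nrow(stability)) {
    stop("n_refs (", n_refs, ") exceeds the number of candidates (",
         nrow(stability), ")")
  }
  stability$symbol[order(stability$rho, stability$symbol)][seq_len(n_refs)]
}

#' Reference-gene normalization
#'
#' Scales each sample so the geometric mean of the reference genes equals
#' the across-sample grand geometric mean of those references.
#'
#' @param screen a (lane-scaled) `count_screen`.
#' @param refs reference gene symbols, present with positive counts in every
#'   sample (or set `pseudo_count`).
#' @param pseudo_count optional pseudo-count for zero reference counts.
#' @return the screen with rescaled counts; per-sample reference factors in
#'   `$provenance$reference_factors`.
#' @export
reference_normalize <- function(screen, refs, pseudo_count = NULL) {
  missing <- setdiff(refs, rownames(screen$counts))
  if (length(missing)) stop("reference gene(s) not in screen: ",
                            paste(missing, collapse = ", "))
  ref_counts <- screen$counts[refs, , drop = FALSE]
  gm <- apply(ref_counts, 2, geomean, pseudo_count = pseudo_count,
              what = "reference count")
  factors <- exp(mean(log(gm))) / gm
  counts <- sweep(screen$counts, 2, factors, "*")
  scaled_screen(screen, counts,
                list(reference_genes = refs, reference_factors = factors))
}

#' Generalized log transform
#'
#' The variance-stabilizing transform
#' `h(x) = log2((x + sqrt(x^2 + c^2)) / 2)`: strictly increasing, equal to
#' `log2(x)` asymptotically for `x >> c`, and bounded-variance near zero.
#' The offset `c` is chosen by policy: `"negctrl"` (default) sets `c` to the
#' mean of all negative-control counts, `"quantile"` to the 5th percentile
#' of measured counts, `"fixed"` to a user value.
#'
#' @param screen a (normalized) `count_screen`.
#' @param offset_policy "negctrl", "quantile" or "fixed".
#' @param c_fixed offset for the fixed policy (> 0).
#' @return an `expression_screen`: list with `expr` (measured genes x
#'   samples, log2-like scale), `panel`, `design`, and `params` recording
#'   the transform offset, policy, provenance of upstream scaling and a
#'   `below_background` flag per gene (median count below mean + 2 sd of the
#'   negative controls; flag only, nothing is filtered).
#' @export
glog_transform <- function(screen, offset_policy = c("negctrl", "quantile",
                                                     "fixed"),
                           c_fixed = NULL) {
  offset_policy <- match.arg(offset_policy)
  meas <- measured_symbols(screen$panel)
  neg <- screen$counts[screen$panel$cls == "negctrl" |
                         screen$panel$cls == "negative_ctrl", , drop = FALSE]
  c_off <- switch(offset_policy,
    negctrl = {
      if (nrow(neg) == 0) stop("negctrl offset policy needs negative controls")
      mean(neg)
    },
    quantile = unname(quantile(screen$counts[meas, ], 0.05)),
    fixed = {
      if (is.null(c_fixed) || c_fixed <= 0) {
        stop("fixed offset policy requires c_fixed > 0")
      }
      c_fixed
    })
  x <- screen$counts[meas, , drop = FALSE]
  expr <- glog(x, c_off)
  below <- rep(NA, length(meas))
  if (nrow(neg) > 0) {
    thr <- mean(neg) + 2 * sd(neg)
    below <- apply(x, 1, median) < thr
  }
  structure(list(
    expr = expr,
    panel = screen$panel,
    design = screen$design,
    params = c(screen$provenance,
               list(glog_c = c_off, offset_policy = offset_policy,
                    below_background = setNames(below, meas)))
  ), class = "expression_screen")
}

#' @rdname glog_transform
#' @param x counts. @param c_off transform offset.
#' @export
glog <- function(x, c_off) {
  log2((x + sqrt(x^2 + c_off^2)) / 2)
}

#' @export
print.expression_screen <- function(x, ...) {
  cat("Expression screen:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples (glog2 scale, c =", signif(x$params$glog_c, 4), ")\n")
  if (!is.null(x$params$reference_genes)) {
    cat("  references:", paste(x$params$reference_genes, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Run the full normalization chain
#'
#' Lane scaling from positive spike-ins, NormFinder reference selection
#' among the housekeeping candidates (grouping by `group_by`, default day),
#' geometric-mean reference normalization, then the generalized log
#' transform. The chain is equivariant to a global rescaling of any single
#' sample.
#'
#' @param screen a `count_screen`.
#' @param n_refs number of reference genes (default 5).
#' @param group_by design column used as the NormFinder grouping variable.
#' @param candidates candidate symbols (default: the panel's housekeeping
#'   candidates).
#' @param offset_policy,c_fixed passed to [glog_transform()].
#' @param pseudo_count pseudo-count applied to zero counts inside geometric
#'   means (its use is recorded in the provenance).
#' @return an `expression_screen`; `params` records lane factors, the
#'   stability table, chosen references and transform parameters.
#' @export
normalize_screen <- function(screen, n_refs = 5L, group_by = "day",
                             candidates = NULL,
                             offset_policy = "negctrl", c_fixed = NULL,
                             pseudo_count = 0.5) {
  lane <- lane_scale_factors(screen, pseudo_count = pseudo_count)
  scaled <- apply_lane_scaling(screen, lane)
  if (is.null(candidates)) {
    candidates <- panel_symbols(screen$panel, cls = "housekeeping_candidate")
  }
  if (length(candidates) < 3) {
    stop("need at least 3 reference candidates; panel has ",
         length(candidates))
  }
  if (!group_by %in% names(screen$design)) {
    stop("grouping variable '", group_by, "' not in the design table")
  }
  ## stability is ranked on provisional glog expression of the candidates
  prov <- glog_transform(scaled, offset_policy = offset_policy,
                         c_fixed = c_fixed)
  stab <- normfinder_stability(prov$expr[candidates, , drop = FALSE],
                               groups = screen$design[[group_by]])
  refs <- select_references(stab, n_refs = n_refs)
  normed <- reference_normalize(scaled, refs, pseudo_count = pseudo_count)
  out <- glog_transform(normed, offset_policy = offset_policy,
                        c_fixed = c_fixed)
  out$params$stability <- stab
  out$params$normfinder_group <- group_by
  out$params$pseudo_count <- pseudo_count
  out
}
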