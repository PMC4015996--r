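## Gene-wise contrasts with empirical-Bayes variance moderation,
## twofold/FDR calling, uniform single-factor consistency sets, and
## contrast overlaps.

#' Fit the gene-wise linear model for one contrast
#'
#' For every gene, fits normalized log2 expression on a donor block plus a
#' condition indicator over the samples of two conditions at one day, and
#' returns the estimated log2 fold change (condition A minus condition B),
#' the residual variance and its degrees of freedom.
#'
#' @param expr an `expression_screen`.
#' @param condition_a,condition_b condition ids (A - B is reported).
#' @param day assay day (default 7).
#' @return data.frame `symbol`, `log2FC`, `s2`, `df`, with the unscaled
#'   standard deviation of the contrast coefficient in
#'   `attr(, "stdev_unscaled")`.
#' @export
fit_genewise_model <- function(expr, condition_a, condition_b, day = 7L) {
  if (condition_a == condition_b) stop("contrast requires two conditions")
  design <- expr$design
  keep <- design$day == day &
    design$condition_id %in% c(condition_a, condition_b)
  design <- design[keep, , drop = FALSE]
  n_a <- sum(design$condition_id == condition_a)
  n_b <- sum(design$condition_id == condition_b)
  if (n_a < 2 || n_b < 2) {
    stop("need at least 2 replicates per condition in the contrast ",
         "(have ", n_a, " vs ", n_b, " at day ", day, ")")
  }
  is_a <- as.numeric(design$condition_id == condition_a)
  donor <- factor(design$donor)
  X <- if (nlevels(donor) > 1) model.matrix(~donor + is_a) else cbind(1, is_a)
  Y <- t(expr$expr[, design$sample_id, drop = FALSE])
  fit <- lm.fit(X, Y)
  p <- fit$rank
  df <- nrow(X) - p
  res <- as.matrix(fit$residuals)
  s2 <- colSums(res^2) / df
  xtxi <- chol2inv(chol(crossprod(X)))
  su <- sqrt(xtxi[p, p])
  out <- data.frame(symbol = colnames(Y),
                    log2FC = unname(coef(fit)[p, ]),
                    s2 = unname(s2), df = df,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "stdev_unscaled") <- su
  out
}

## Newton inversion of the trigamma function (for the moment-matching fit
## of the variance prior).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Assumes the gene-wise residual variances follow a scaled F distribution
#' `s^2 ~ s0^2 F(df, d0)` and estimates the prior degrees of freedom `d0`
#' and prior variance `s0^2` by matching the moments of `log s^2` via
#' digamma/trigamma inversion. The posterior (moderated) variance of each
#' gene is `(d0 s0^2 + df s^2) / (d0 + df)`; moderated t statistics built
#' on it carry `df + d0` degrees of freedom. When the observed log
#' variances are no more dispersed than chi-square sampling alone, `d0` is
#' infinite and every posterior variance equals `s0^2`.
#'
#' @param s2 gene-wise residual variances (>= 10 genes).
#' @param df their residual degrees of freedom (scalar).
#' @return list with `d0`, `s02`, `s2_post`.
#' @export
moderate_variance <- function(s2, df) {
  if (length(s2) < 10) stop("need at least 10 genes to estimate the prior")
  s2_work <- s2
  if (any(s2_work <= 0)) {
    floor_val <- if (any(s2_work > 0)) min(s2_work[s2_work > 0]) / 2 else 1e-8
    s2_work[s2_work <= 0] <- floor_val
  }
  z <- log(s2_work)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
    s2_post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_(j >= i) p_(j) m / j`, capped at 1, returned in the
#' original order.
#'
#' @param p p-values in [0, 1].
#' @return adjusted values (q-values) of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
}

#' Apply fold-change and FDR cut-offs
#'
#' A gene is significant iff `|log2FC| >= fc_threshold` (default 1, i.e. a
#' twofold difference on the log2-like scale) and `q < q_threshold`
#' (default FDR 5%).
#'
#' @param results data.frame with columns `log2FC` and `q`.
#' @param fc_threshold log2 fold-change cut-off (> 0).
#' @param q_threshold FDR cut-off (> 0).
#' @return the data.frame with `direction` ("up"/"down") and `significant`
#'   columns set.
#' @export
call_de <- function(results, fc_threshold = 1, q_threshold = 0.05) {
  if (fc_threshold <= 0 || q_threshold <= 0) stop("thresholds must be > 0")
  results$direction <- ifelse(results$log2FC >= 0, "up", "down")
  results$significant <- abs(results$log2FC) >= fc_threshold &
    results$q < q_threshold
  results
}

#' Run one moderated contrast end to end
#'
#' Gene-wise fit, empirical-Bayes moderation, ordinary and moderated t,
#' BH adjustment across genes within the contrast, and twofold/FDR calling.
#'
#' @param expr an `expression_screen`.
#' @param condition_a,condition_b condition ids (log2FC is A minus B).
#' @param day assay day.
#' @param moderated use the moderated t (default) or the ordinary t.
#' @param fc_threshold,q_threshold passed to [call_de()].
#' @return a `de_result` data.frame: `symbol`, `log2FC`, `t_ord`, `t_mod`,
#'   `p`, `q`, `direction`, `significant`; moderation hyperparameters in
#'   `attr(, "moderation")`.
#' @export
de_contrast <- function(expr, condition_a, condition_b, day = 7L,
                        moderated = TRUE, fc_threshold = 1,
                        q_threshold = 0.05) {
  fit <- fit_genewise_model(expr, condition_a, condition_b, day = day)
  su <- attr(fit, "stdev_unscaled")
  mod <- moderate_variance(fit$s2, fit$df[1])
  t_ord <- fit$log2FC / (sqrt(fit$s2) * su)
  t_mod <- fit$log2FC / (sqrt(mod$s2_post) * su)
  if (moderated) {
    df_total <- fit$df[1] + mod$d0
    p <- 2 * pt(-abs(t_mod), df = df_total)
  } else {
    p <- 2 * pt(-abs(t_ord), df = fit$df[1])
  }
  out <- data.frame(symbol = fit$symbol, log2FC = fit$log2FC,
                    t_ord = t_ord, t_mod = t_mod, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE)
  out <- call_de(out, fc_threshold = fc_threshold, q_threshold = q_threshold)
  attr(out, "moderation") <- mod[c("d0", "s02")]
  attr(out, "contrast") <- c(A = condition_a, B = condition_b, day = day)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Genes uniformly regulated by a single factor
#'
#' A gene belongs to a factor's uniform set when it is called significant
#' (twofold and FDR, via [call_de()]) against the no-factor baseline
#' condition 32 in all 16 factorial conditions containing the factor, with
#' the same direction in all of them.
#'
#' @param expr an `expression_screen`.
#' @param registry a `condition_registry`.
#' @param factor_name one of `SCREEN_FACTORS`.
#' @param day assay day.
#' @param baseline_id baseline condition (default 32).
#' @param ... thresholds passed to [de_contrast()].
#' @return list with `up` and `down` symbol vectors.
#' @export
uniform_factor_genes <- function(expr, registry, factor_name, day = 7L,
                                 baseline_id = 32L, ...) {
  if (!factor_name %in% SCREEN_FACTORS) {
    stop("unknown factor: ", factor_name, "; expected one of ",
         paste(SCREEN_FACTORS, collapse = ", "))
  }
  fact_ids <- registry$id[registry$arm == "factorial"]
  pres <- condition_presence(registry, fact_ids)
  with_ids <- fact_ids[pres[, factor_name]]
  res <- lapply(with_ids, function(cid) {
    de_contrast(expr, cid, baseline_id, day = day, ...)
  })
  sig_up <- lapply(res, function(r) r$symbol[r$significant &
                                               r$direction == "up"])
  sig_dn <- lapply(res, function(r) r$symbol[r$significant &
                                               r$direction == "down"])
  list(up = Reduce(intersect, sig_up), down = Reduce(intersect, sig_dn))
}

#' Overlap between two contrasts' significant gene sets
#'
#' @param a,b `de_result`s over the same gene universe.
#' @return list with `n_a`, `n_b`, `n_overlap`, the shared symbols, and the
#'   same counts split by direction.
#' @export
contrast_overlap <- function(a, b) {
  if (!setequal(a$symbol, b$symbol)) {
    stop("contrasts cover different gene universes")
  }
  sig_a <- a$symbol[a$significant]
  sig_b <- b$symbol[b$significant]
  by_dir <- lapply(c(up = "up", down = "down"), function(d) {
    sa <- a$symbol[a$significant & a$direction == d]
    sb <- b$symbol[b$significant & b$direction == d]
    list(n_a = length(sa), n_b = length(sb),
         n_overlap = length(intersect(sa, sb)))
  })
  list(n_a = length(sig_a), n_b = length(sig_b),
       n_overlap = length(intersect(sig_a, sig_b)),
       overlap = intersect(sig_a, sig_b),
       by_direction = by_dir)
}
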