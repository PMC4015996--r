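## Factorial effect inference on marker-score responses: effect estimation
## (least squares and Yates contrasts), standardized-effect tests with
## normal-plot coordinates, Box-Cox response transformation, and 2x2
## interaction summaries.

#' Yates-contrast effects for an arbitrary two-level design
#'
#' Direct contrast computation of all main effects and interactions of a
#' (replicated) full 2^k design: the effect of a term is
#' `sum(sign * y) / (2^(k-1) * replicates)`, where the sign of a run is the
#' product of its ±1 factor codes over the term's factors. Serves as the
#' contrast route that the regression-based [estimate_effects()] must
#' reproduce.
#'
#' @param y responses, one per run.
#' @param levels n x k matrix of 0/1 factor levels (rows = runs; every one
#'   of the 2^k cells must appear equally often).
#' @param max_order highest interaction order (default k).
#' @return named numeric of effects, terms joined by ":".
#' @export
yates_effects <- function(y, levels, max_order = ncol(levels)) {
  k <- ncol(levels)
  if (length(y) != nrow(levels)) {
    stop("levels must form a complete (equally replicated) 2^k design ",
         "with one response per run")
  }
  if (is.null(colnames(levels))) colnames(levels) <- LETTERS[seq_len(k)]
  cells <- apply(levels, 1, paste, collapse = "")
  if (length(unique(table(cells))) != 1 || length(unique(cells)) != 2^k) {
    stop("levels must form a complete (equally replicated) 2^k design")
  }
  reps <- nrow(levels) / 2^k
  coded <- 2 * levels - 1
  out <- numeric(0)
  for (ord in seq_len(min(max_order, k))) {
    for (idx in utils::combn(k, ord, simplify = FALSE)) {
      sign <- apply(coded[, idx, drop = FALSE], 1, prod)
      out[paste(colnames(levels)[idx], collapse = ":")] <-
        sum(sign * y) / (2^(k - 1) * reps)
    }
  }
  out
}

check_complete_factorial <- function(responses) {
  tab <- table(responses$condition_id, responses$donor)
  if (nrow(tab) != 32 || any(tab != 1)) {
    stop("effect estimation needs the complete 2^5 factorial arm with one ",
         "observation per (condition, donor)")
  }
  if (ncol(tab) < 2) stop("need at least 2 replicates (donors)")
}

#' Estimate factorial effects
#'
#' Estimates all main effects and interactions up to `max_order` from
#' per-(condition, donor) responses over the complete 2^5 factorial arm,
#' with donor as a block. The effect of a term is the mean response at its
#' high level minus the mean at its low level, computed two ways that must
#' agree to numerical precision: (a) twice the least-squares coefficient of
#' the ±1-coded column, and (b) the Yates contrast divided by
#' 2^(k-1) x replicates. Interactions above `max_order` are pooled into the
#' residual.
#'
#' @param responses data.frame with columns `condition_id`, `donor` and the
#'   response in `value_col`.
#' @param registry a `condition_registry`.
#' @param value_col response column name (default "wanted").
#' @param max_order highest interaction order (1..3, default 3).
#' @return an `effect_table` data.frame: `term`, `order`, `effect`,
#'   `effect_yates`; residual variance, residual df and design size are
#'   carried in attributes for [test_effects()].
#' @export
estimate_effects <- function(responses, registry, value_col = "wanted",
                             max_order = 3L) {
  check_complete_factorial(responses)
  y <- responses[[value_col]]
  if (is.null(y)) stop("no response column '", value_col, "'")
  design <- data.frame(sample_id = sprintf("r%03d", seq_len(nrow(responses))),
                       condition_id = responses$condition_id,
                       donor = responses$donor,
                       day = NA_integer_, lane = NA_integer_)
  class(design) <- c("design_table", "data.frame")
  mm <- encode_model_matrix(design, registry, max_order = max_order)
  X <- mm$X
  N <- nrow(X)
  fit <- lm.fit(X, y)
  coefs <- coef(fit)[mm$effect_cols]
  effect_ls <- 2 * coefs
  ## independent route: explicit Yates contrasts
  reps <- N / 32
  effect_yates <- vapply(mm$effect_cols, function(tm) {
    sum(X[, tm] * y) / (2^4 * reps)
  }, numeric(1))
  rss <- sum(fit$residuals^2)
  ## saturated fits: round pure floating-point residue down to exact zero
  if (rss < 1e-20 * max(sum(y^2), 1)) rss <- 0
  df_resid <- N - fit$rank
  out <- data.frame(term = mm$terms$term, order = mm$terms$order,
                    effect = unname(effect_ls),
                    effect_yates = unname(effect_yates),
                    stringsAsFactors = FALSE)
  attr(out, "sigma2") <- rss / df_resid
  attr(out, "df_resid") <- df_resid
  attr(out, "n_obs") <- N
  attr(out, "response") <- value_col
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Test standardized effects and lay out the normal plot
#'
#' Standard errors come from the replicate-based residual mean square of
#' the blocked factorial fit (donor block and all modeled terms removed;
#' higher-order interactions pooled into error): `SE = 2
#' sqrt(sigma^2 / N)`. The standardized effect is `t = effect / SE` with a
#' two-sided p-value on the residual df. Normal-plot coordinates pair the
#' ordered standardized effects with normal quantiles at
#' `(i - 0.375) / (n + 0.25)`.
#'
#' @param table an `effect_table` from [estimate_effects()].
#' @param alpha significance level (default 0.05; no multiplicity
#'   correction across terms).
#' @return the table with columns `se`, `t`, `p`, `significant` added and a
#'   `normal_plot` attribute (data.frame `term`, `t`, `quantile`).
#' @export
test_effects <- function(table, alpha = 0.05) {
  sigma2 <- attr(table, "sigma2")
  df_resid <- attr(table, "df_resid")
  N <- attr(table, "n_obs")
  if (is.null(sigma2)) stop("table lacks fit attributes; use estimate_effects")
  if (df_resid < 1) {
    stop("zero residual degrees of freedom: pool higher-order terms into ",
         "the error (lower max_order)")
  }
  se <- 2 * sqrt(sigma2 / N)
  table$se <- se
  if (se == 0) {
    ## saturated (noise-free) responses: zero effects are null, others exact
    tol <- 1e-12 * max(1, abs(table$effect))
    table$t <- ifelse(abs(table$effect) < tol, 0,
                      sign(table$effect) * Inf)
    table$effect[abs(table$effect) < tol] <- 0
  } else {
    table$t <- table$effect / se
  }
  table$p <- 2 * pt(-abs(table$t), df = df_resid)
  table$significant <- table$p < alpha
  ord <- order(table$t)
  n <- nrow(table)
  attr(table, "alpha") <- alpha
  attr(table, "normal_plot") <- data.frame(
    term = table$term[ord],
    t = table$t[ord],
    quantile = qnorm((seq_len(n) - 0.375) / (n + 0.25))
  )
  table
}

#' Box-Cox response transformation
#'
#' Profile-likelihood choice of the Box-Cox exponent on the grid [-2, 2] in
#' steps of 0.01, applied to (shifted) positive responses. With
#' `lambda = 0` the transform is `log(y)`; otherwise `(y^lambda - 1) /
#' lambda` (so `lambda = 1` is the affine identity `y - 1`).
#'
#' @param responses numeric responses.
#' @param shift added to the responses first; they must then be positive.
#' @return list with `lambda`, `transformed`, `shift`.
#' @export
boxcox_transform <- function(responses, shift = 0) {
  y <- responses + shift
  if (any(y <= 0)) {
    stop("responses must be positive after the shift; ",
         "supply a larger shift")
  }
  grid <- seq(-2, 2, by = 0.01)
  prof <- MASS::boxcox(y ~ 1, lambda = grid, plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  transformed <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  list(lambda = lambda, transformed = transformed, shift = shift)
}

#' 2x2 interaction cell means
#'
#' Mean response in the four presence/absence cells of a factor pair,
#' averaged over the remaining factors and donors, with the synergy index
#' `both - a_only - b_only + neither` (zero under additivity).
#'
#' @param responses data.frame as in [estimate_effects()].
#' @param registry a `condition_registry`.
#' @param pair two factor names from `SCREEN_FACTORS`.
#' @param value_col response column.
#' @return list with `cells` (2x2 matrix, rows = first factor absent/
#'   present) and `synergy`.
#' @export
interaction_summary <- function(responses, registry, pair,
                                value_col = "wanted") {
  if (length(pair) != 2 || !all(pair %in% SCREEN_FACTORS)) {
    stop("pair must name two of: ", paste(SCREEN_FACTORS, collapse = ", "))
  }
  check_complete_factorial(responses)
  pres <- condition_presence(registry, responses$condition_id)
  a <- pres[, pair[1]]
  b <- pres[, pair[2]]
  y <- responses[[value_col]]
  cells <- matrix(c(mean(y[!a & !b]), mean(y[!a & b]),
                    mean(y[a & !b]), mean(y[a & b])),
                  2, 2, byrow = TRUE,
                  dimnames = list(paste0(pair[1], c("-", "+")),
                                  paste0(pair[2], c("-", "+"))))
  synergy <- cells[2, 2] - cells[2, 1] - cells[1, 2] + cells[1, 1]
  list(cells = cells, synergy = synergy)
}
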