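contrast_expr <- function(values_a, values_b, n_extra = 12, seed = 31L) {
  # two-condition day-7 screen with 3 donors; values_* are per-gene means
  d <- data.frame(sample_id = sprintf("s%d", 1:6),
                  condition_id = rep(c(12L, 16L), each = 3),
                  donor = rep(1:3, 2), day = 7L, lane = 1:6)
  class(d) <- c("design_table", "data.frame")
  genes <- c(names(values_a), sprintf("X%02d", seq_len(n_extra)))
  expr <- matrix(8, length(genes), 6, dimnames = list(genes, d$sample_id))
  expr[names(values_a), 1:3] <- matrix(values_a, ncol = 3)
  expr[names(values_a), 4:6] <- matrix(values_b, ncol = 3)
  expr <- expr + withr::with_seed(seed, matrix(rnorm(length(expr), 0, 0.1),
                                               nrow(expr)))
  panel <- data.frame(symbol = genes, cls = "endogenous",
                      marker_set = "other", stringsAsFactors = FALSE)
  class(panel) <- c("gene_panel", "data.frame")
  structure(list(expr = expr, panel = panel, design = d,
                 params = list(glog_c = 1)),
            class = "expression_screen")
}

test_that("the gene-wise fit returns exact fold changes and variances", {
  ex <- contrast_expr(c(G = 7), c(G = 5), seed = 32L)
  ex$expr["G", ] <- c(7, 7, 7, 5, 5, 5)   # exact replicate triples
  fit <- fit_genewise_model(ex, 12, 16)
  g <- fit[fit$symbol == "G", ]
  expect_equal(g$log2FC, 2)
  expect_equal(g$s2, 0)
  # antisymmetry under swapping the contrast
  swap <- fit_genewise_model(ex, 16, 12)
  expect_equal(swap$log2FC, -fit$log2FC)
  expect_equal(swap$s2, fit$s2)
  expect_error(fit_genewise_model(ex, 12, 12), "two conditions")
  expect_error(fit_genewise_model(ex, 12, 31), "replicates")
})

test_that("planted fold changes are recovered through the pipeline", {
  est <- vapply(1:50, function(s) {
    cfg <- fact7_config(s, effects = list(planted_effect("COL2A1", "DEX",
                                                         1.5)))
    expr <- normalize_screen(simulate_counts(cfg)$screen)
    fit <- fit_genewise_model(expr, 12, 16)
    fit$log2FC[fit$symbol == "COL2A1"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.5), 0.2)
})

test_that("variance moderation matches its generative model and limits", {
  # identical variances: infinite prior df, posterior collapses to s0^2
  m_inf <- moderate_variance(rep(0.4, 50), df = 4)
  expect_identical(m_inf$d0, Inf)
  expect_equal(m_inf$s2_post, rep(m_inf$s02, 50))

  # enormous spread: prior df near zero, posterior follows the data
  set.seed(51)
  s2_wide <- exp(rnorm(3000, 0, 12))
  m0 <- moderate_variance(s2_wide, df = 8)
  expect_lt(m0$d0, 0.2)
  expect_lt(median(abs(m0$s2_post - s2_wide) / s2_wide), 0.05)

  # hyperparameter recovery from the scaled inverse-chi-square prior
  rec <- t(vapply(1:20, function(s) {
    set.seed(s)
    sg <- 4 * 0.05 / rchisq(2000, 4)
    s2 <- sg * rchisq(2000, 4) / 4
    m <- moderate_variance(s2, 4)
    c(m$d0, m$s02)
  }, numeric(2)))
  expect_gte(mean(rec[, 1]), 3)
  expect_lte(mean(rec[, 1]), 5.3)
  expect_lt(abs(mean(rec[, 2]) - 0.05) / 0.05, 0.2)

  expect_error(moderate_variance(rep(1, 5), 4), "at least 10")
})

test_that("moderation agrees with the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(52)
  s2 <- 0.05 * 4 / rchisq(500, 4) * rchisq(500, 6) / 6
  mine <- moderate_variance(s2, 6)
  ref <- limma::squeezeVar(s2, 6)
  expect_equal(mine$d0, ref$df.prior, tolerance = 1e-8)
  expect_equal(mine$s02, ref$var.prior, tolerance = 1e-8)
  expect_equal(mine$s2_post, ref$var.post, tolerance = 1e-8)
})

test_that("BH adjustment implements the step-up definition exactly", {
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.08 / 3, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.03, 7)), rep(0.03, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # brute-force step-up oracle on random vectors, plus the stats reference
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)              # ascending: p[o[j]] is the j-th smallest
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(1, p[o[i:m]] * m / seq(i, m))
    }
    q
  }
  set.seed(61)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("twofold/FDR calling applies both cut-offs", {
  res <- data.frame(log2FC = c(0.9, 2, -1.5, 1.2, 0.2),
                    q = c(0.001, 0.049, 0.03, 0.2, 0.01))
  out <- call_de(res)
  expect_equal(out$significant, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$direction[2:3], c("up", "down"))

  # a constructed ten-gene toy with exactly three passing genes
  toy <- data.frame(log2FC = c(2, -2, 1.1, 0.5, 3, 0.9, -0.95, 1.8, 0, -4),
                    q = c(0.01, 0.04, 0.049, 0.001, 0.2, 0.01, 0.01, 0.06,
                          0.01, 0.5))
  expect_equal(sum(call_de(toy)$significant), 3)
  expect_error(call_de(res, fc_threshold = 0), "> 0")
})

test_that("de_contrast is internally consistent and null-calibrated", {
  nl <- cached_null_expr()
  de <- de_contrast(nl$expr, 12, 16)
  expect_equal(de$q, bh_adjust(de$p))
  expect_equal(de$significant, abs(de$log2FC) >= 1 & de$q < 0.05)
  mod <- attr(de, "moderation")
  expect_true(mod$d0 > 0 && mod$s02 > 0)

  # under the null the FDR-controlled call fraction stays below its level
  fr <- vapply(1:40, function(s) {
    expr <- normalize_screen(simulate_null_screen(fact7_config(900 + s))$screen)
    mean(de_contrast(expr, 12, 16)$q < 0.05)
  }, numeric(1))
  expect_lte(mean(fr), 0.05)
})

test_that("uniform single-factor sets demand all-16 consistent calls", {
  # g_all: down 2 in every DEX condition; g_one: misses one DEX condition;
  # g_mixed: down in half, up in the other half
  dex_ids <- REG$id[REG$arm == "factorial"][
    condition_presence(REG, REG$id[REG$arm == "factorial"])[, "DEX"]]
  flip <- dex_ids[5]
  half_up <- dex_ids[1:8]
  deltas <- list(
    g_all = function(cond) if (isTRUE(cond$DEX)) -2 else 0,
    g_one = function(cond) {
      if (isTRUE(cond$DEX) && cond$id != flip) -2 else 0
    },
    g_mixed = function(cond) {
      if (isTRUE(cond$DEX)) (if (cond$id %in% half_up) 2 else -2) else 0
    }
  )
  ex <- manual_expr_screen(deltas)
  uni <- uniform_factor_genes(ex, REG, "DEX")
  expect_true("g_all" %in% uni$down)
  expect_false("g_one" %in% c(uni$up, uni$down))
  expect_false("g_mixed" %in% c(uni$up, uni$down))
  expect_error(uniform_factor_genes(ex, REG, "NOPE"), "unknown factor")
})

test_that("contrast overlaps count shared significant genes by direction", {
  mk <- function(sig_syms, dirs) {
    df <- data.frame(symbol = sprintf("g%d", 1:10),
                     log2FC = 0, q = 1, stringsAsFactors = FALSE)
    df$log2FC[match(sig_syms, df$symbol)] <- ifelse(dirs == "up", 2, -2)
    df$q[match(sig_syms, df$symbol)] <- 0.01
    call_de(df)
  }
  a <- mk(paste0("g", 1:5), rep("up", 5))
  b <- mk(paste0("g", 3:7), rep("up", 5))
  ov <- contrast_overlap(a, b)
  expect_equal(ov$n_overlap, 3)
  expect_equal(ov$n_a, 5)
  self <- contrast_overlap(a, a)
  expect_equal(self$n_overlap, self$n_a)
  expect_equal(ov$by_direction$down$n_overlap, 0)
  b2 <- mk("g9", "up")
  b2$symbol[1] <- "other"
  expect_error(contrast_overlap(a, b2), "different gene universes")
})

test_that("planted contrast structure is recovered with its overlap", {
  panel <- build_default_panel(139L, seed = 1L)
  filler <- panel_symbols(panel, cls = "endogenous", marker_set = "other")
  both <- filler[1:40]
  a_only <- filler[41:60]
  b_only <- filler[61:80]
  effects <- c(
    lapply(seq_along(both), function(i) {
      planted_effect(both[i], "DEX", ifelse(i %% 2, 1.5, -1.5))
    }),
    unlist(recursive = FALSE, lapply(seq_along(a_only), function(i) list(
      planted_effect(a_only[i], "DEX", ifelse(i %% 2, 1.5, -1.5)),
      planted_effect(a_only[i], "DEX:BMP", ifelse(i %% 2, -1.5, 1.5))))),
    lapply(seq_along(b_only), function(i) {
      planted_effect(b_only[i], "DEX:BMP", ifelse(i %% 2, 1.5, -1.5))
    })
  )
  counts <- t(vapply(1:20, function(s) {
    cfg <- sim_config(panel, REG, seed = s, days = 7L, include_day0 = FALSE,
                      arms = "factorial", effects = effects)
    expr <- normalize_screen(simulate_counts(cfg)$screen)
    ov <- contrast_overlap(de_contrast(expr, 12, 16),
                           de_contrast(expr, 11, 15))
    c(ov$n_a, ov$n_b, ov$n_overlap)
  }, numeric(3)))
  means <- colMeans(counts)
  expect_lt(abs(means[1] - 60) / 60, 0.15)
  expect_lt(abs(means[2] - 60) / 60, 0.15)
  expect_lt(abs(means[3] - 40) / 40, 0.15)
})

test_that("the DEX-dependent bone gene lands in the uniform down-set", {
  run <- cached_paper_run()
  bglap <- attr(run$cfg, "analogs")[["BGLAP"]]
  uni <- uniform_factor_genes(run$expr, REG, "DEX")
  expect_true(bglap %in% uni$down)
})
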