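test_that("lane factors equalize positive-control geometric means", {
  sim <- simulate_counts(fact7_config(31L, lane_sd = 0,
                                      control_dispersion = 0))
  # identical positive-control columns: all factors are 1
  f <- lane_scale_factors(sim$screen)
  expect_equal(unname(f), rep(1, length(f)), tolerance = 1e-12)

  # a uniformly rescaled sample gets the exactly inverse factor (doubling
  # keeps the counts integral; halving is the mirror image)
  doubled <- sim$screen
  doubled$counts[, 1] <- doubled$counts[, 1] * 2L
  f2 <- lane_scale_factors(doubled)
  expect_equal(unname(f2[1] / f2[2]), 0.5, tolerance = 1e-12)

  # zero positive-control counts break the geometric mean unless a
  # pseudo-count is configured
  zeroed <- sim$screen
  zeroed$counts[which(zeroed$panel$cls == "positive_ctrl")[1], 1] <- 0L
  expect_error(lane_scale_factors(zeroed), "pseudo_count")
  expect_silent(lane_scale_factors(zeroed, pseudo_count = 0.5))
})

test_that("estimated lane factors track the simulated lane effects", {
  rs <- vapply(1:10, function(s) {
    d <- build_design_table(REG, n_donors = 3, days = 7L,
                            include_day0 = FALSE, arms = "factorial")
    d <- d[1:48, ]
    class(d) <- c("design_table", "data.frame")
    cfg <- null_config(small_panel(), REG, seed = s, design = d)
    sim <- simulate_counts(cfg)
    cor(-log(lane_scale_factors(sim$screen)), sim$truth$lane_log)
  }, numeric(1))
  expect_gte(mean(rs), 0.95)
})

test_that("stability model ranks candidates and degenerates correctly", {
  # exactly constant candidates: zero intra- and inter-group variation,
  # lexicographic tie-break puts the alphabetically first at rank 1
  X <- rbind(c1 = rep(5, 8), c3 = rep(9, 8), c2 = rep(7, 8))
  st <- normfinder_stability(X, rep(c("a", "b"), each = 4))
  expect_equal(st$rho, rep(0, 3))
  expect_equal(st$symbol[st$rank == 1], "c1")

  # single group: inter-group term vanishes, ranking = residual variance
  set.seed(42)
  sds <- c(0.01, 0.3, 0.1, 0.6)
  X1 <- t(sapply(sds, function(s) rnorm(20, 10, s)))
  rownames(X1) <- paste0("g", seq_along(sds))
  st1 <- normfinder_stability(X1, rep("one", 20))
  expect_equal(st1$inter_d, rep(0, 4))
  # the reduction: stability collapses onto the residual variance exactly
  expect_equal(st1$rho, st1$intra_sd)
  expect_equal(st1$rank, rank(st1$intra_sd))

  expect_error(normfinder_stability(X[1:2, ], rep("a", 8)), "at least 3")
  expect_error(normfinder_stability(X, c("a", rep("b", 7))), "at least 2")
})

test_that("stability rank recovers the per-gene noise ordering", {
  sp <- vapply(1:20, function(s) {
    set.seed(s)
    sds <- seq(0, 0.5, by = 0.1)
    X <- t(sapply(sds, function(sd) rnorm(30, 10, 0.05) + rnorm(30, 0, sd)))
    rownames(X) <- paste0("c", seq_along(sds))
    st <- normfinder_stability(X, rep(c("a", "b"), length.out = 30))
    cor(st$rank[match(rownames(X), st$symbol)], rank(sds),
        method = "spearman")
  }, numeric(1))
  expect_gte(mean(sp), 0.9)
})

test_that("reference selection takes the most stable candidates", {
  st <- data.frame(symbol = c("B", "A", "C", "D"),
                   rho = c(0.2, 0.2, 0.1, 0.5))
  expect_equal(select_references(st, 2), c("C", "A"))
  expect_equal(select_references(st, 4), c("C", "A", "B", "D"))
  expect_error(select_references(st, 5), "exceeds")

  # the pipeline default asks for five references
  expect_equal(eval(formals(normalize_screen)$n_refs), 5L)
})

test_that("reference normalization equalizes the reference geometric mean", {
  sim <- simulate_counts(fact7_config(32L))
  refs <- panel_symbols(sim$screen$panel, cls = "housekeeping_candidate")[1:5]

  # a sample scaled by 4 is divided by 4 exactly (up to the common grand
  # geometric-mean target, which every sample shares)
  scaled <- sim$screen
  scaled$counts[, 2] <- scaled$counts[, 2] * 4L
  out <- reference_normalize(scaled, refs)
  out0 <- reference_normalize(sim$screen, refs)
  n <- ncol(sim$screen$counts)
  expect_equal(out$counts, out0$counts * 4^(1 / n), tolerance = 1e-10)

  # post-condition: reference geomean constant across samples
  gm <- apply(out$counts[refs, ], 2, factoscreen:::geomean)
  expect_lt(diff(range(gm)) / mean(gm), 1e-12)

  # already-equal references leave the matrix unchanged
  flat <- sim$screen
  flat$counts[refs, ] <- 100L
  expect_equal(reference_normalize(flat, refs)$counts, flat$counts * 1.0)
  expect_error(reference_normalize(sim$screen, "NOPE"), "not in screen")
})

test_that("glog matches its closed forms and flattens count variance", {
  expect_equal(glog(0, 7), log2(7 / 2))
  expect_lt(abs(glog(2^20, 10) - 20), 1e-4)
  x <- seq(0, 100, by = 0.5)
  expect_true(all(diff(glog(x, 5)) > 0))

  # variance flattening: replicate SD at low vs high mean stays within 3x
  # under the glog, and beats plain log2(x + 1)
  ratios <- vapply(1:10, function(s) {
    set.seed(s)
    lo <- rnbinom(200, mu = 5, size = 20)
    hi <- rnbinom(200, mu = 5000, size = 20)
    c(sd(glog(lo, 10)) / sd(glog(hi, 10)),
      sd(log2(lo + 1)) / sd(log2(hi + 1)))
  }, numeric(2))
  expect_lt(mean(ratios[1, ]), 3)
  expect_lt(mean(ratios[1, ]), mean(ratios[2, ]))

  sim <- simulate_counts(fact7_config(33L))
  expect_error(glog_transform(sim$screen, offset_policy = "fixed"),
               "c_fixed")
  ex <- glog_transform(sim$screen, offset_policy = "fixed", c_fixed = 4)
  expect_equal(ex$params$glog_c, 4)
  expect_true(all(is.finite(ex$expr)))
})

test_that("the normalization chain is equivariant to sample rescaling", {
  sim <- simulate_counts(fact7_config(34L))
  base <- normalize_screen(sim$screen)
  rescaled <- sim$screen
  rescaled$counts[, 5] <- rescaled$counts[, 5] * 3L
  redo <- normalize_screen(rescaled)
  # lane scaling undoes the rescaling exactly; all that remains is the
  # common grand-geometric-mean shift of log2(3)/n shared by every entry
  shift <- redo$expr - base$expr
  expect_lt(max(abs(shift - log2(3) / ncol(base$expr))), 1e-8)
})

test_that("selected references are the planted stable housekeepers", {
  run <- cached_paper_run()
  hk <- run$sim$truth$housekeeping
  # default candidate pool
  expect_true(all(run$expr$params$reference_genes %in% hk))
  # against endogenous intruder candidates, stability still prefers the
  # low-variance housekeepers
  hits <- vapply(1:5, function(s) {
    cfg <- paper_like_config(run$panel, REG, seed = 200L + s)
    sim <- simulate_counts(cfg)
    prov <- glog_transform(apply_lane_scaling(sim$screen))
    set.seed(s)
    intruders <- sample(panel_symbols(run$panel, cls = "endogenous",
                                      marker_set = "other"), 10)
    st <- normfinder_stability(prov$expr[c(hk, intruders), ],
                               sim$screen$design$day)
    sum(select_references(st, 5) %in% hk)
  }, numeric(1))
  expect_true(all(hits >= 4))
})

test_that("below-background genes are flagged, not filtered", {
  cfg <- fact7_config(35L, baseline_mean = 400)
  sim <- simulate_counts(cfg)
  # push one gene into the negative-control range
  dim_gene <- panel_symbols(sim$screen$panel, cls = "endogenous",
                            marker_set = "other")[1]
  sim$screen$counts[dim_gene, ] <- 1L
  ex <- normalize_screen(sim$screen)
  expect_true(ex$params$below_background[[dim_gene]])
  expect_true(dim_gene %in% rownames(ex$expr))
  expect_false(any(ex$params$below_background[WANTED_MARKERS]))
})
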