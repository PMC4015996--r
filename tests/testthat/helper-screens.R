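# Shared fixtures, built in code. Heavier simulated objects are cached per
# test run.

REG <- build_condition_registry()

small_panel <- function() build_default_panel(40L, seed = 1L)

# factorial-arm-only, day-7-only config: the cheap unit-test workhorse
# (no planted effects unless supplied)
fact7_config <- function(seed, panel = small_panel(), gene_log2_sd = 1.5,
                         ...) {
  sim_config(panel, REG, seed = seed, days = 7L, include_day0 = FALSE,
             arms = "factorial", gene_log2_sd = gene_log2_sd, ...)
}

.screen_cache <- new.env(parent = emptyenv())

# one paper-like full screen (364 genes, 3 donors, days 0/1/7), normalized
cached_paper_run <- function() {
  if (is.null(.screen_cache$paper)) {
    panel <- build_default_panel(364L, seed = 1L)
    cfg <- paper_like_config(panel, REG, seed = 101L)
    sim <- simulate_counts(cfg)
    .screen_cache$paper <- list(panel = panel, cfg = cfg, sim = sim,
                                expr = normalize_screen(sim$screen))
  }
  .screen_cache$paper
}

# a small normalized null screen for structural tests
cached_null_expr <- function() {
  if (is.null(.screen_cache$null)) {
    sim <- simulate_null_screen(fact7_config(7L))
    .screen_cache$null <- list(sim = sim, expr = normalize_screen(sim$screen))
  }
  .screen_cache$null
}

# hand-built expression screen: factorial arm, day 7, 3 donors, with exact
# per-gene log2 deltas per condition plus small deterministic noise
manual_expr_screen <- function(deltas, n_filler = 12L, noise_sd = 0.05,
                               seed = 99L) {
  # deltas: named list symbol -> function(condition_row) log2 shift
  design <- build_design_table(REG, n_donors = 3L, days = 7L,
                               include_day0 = FALSE, arms = "factorial")
  symbols <- c(names(deltas), sprintf("FILL%02d", seq_len(n_filler)))
  expr <- matrix(10, length(symbols), nrow(design),
                 dimnames = list(symbols, design$sample_id))
  for (j in seq_len(nrow(design))) {
    cond <- lookup_condition(REG, design$condition_id[j])
    for (g in names(deltas)) {
      expr[g, j] <- expr[g, j] + deltas[[g]](cond)
    }
  }
  expr <- expr + withr::with_seed(seed, {
    matrix(rnorm(length(expr), 0, noise_sd), nrow(expr))
  })
  panel <- data.frame(symbol = symbols, cls = "endogenous",
                      marker_set = "other", stringsAsFactors = FALSE)
  class(panel) <- c("gene_panel", "data.frame")
  structure(list(expr = expr, panel = panel, design = design,
                 params = list(glog_c = 1)),
            class = "expression_screen")
}
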