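## Negative-binomial count simulator with planted factorial effect structure.
## This is the ground-truth stand-in for a digital-counting screen: every
## downstream stage (normalization, scoring, effect inference, DE,
## enrichment, PCA) is tested against the generative parameters used here.

#' Describe a planted effect
#'
#' A planted effect adds `log2_effect` to the generative log2 mean of its
#' target genes in every sample whose condition activates `term` and whose
#' day is in `days`.
#'
#' @param target a gene symbol vector, or one of "wanted"/"unwanted" to
#'   target a whole marker set.
#' @param term a factor term: one of "TGFB1", "TGFB2", "TGFB3", "TGFB" (any
#'   isoform), "BMP2", "BMP4", "BMP6", "BMP" (any isoform), "DEX", "IGF1",
#'   "FGF2", an interaction joined by ":" (active when all parts are
#'   present, e.g. "TGFB:DEX"), or "day" (active in every treated sample).
#' @param log2_effect signed effect size in log2 counts.
#' @param days day scope, subset of c(1, 7).
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(target, term, log2_effect, days = c(1, 7)) {
  structure(list(target = target, term = term,
                 log2_effect = log2_effect, days = days),
            class = "planted_effect")
}

#' Simulation configuration
#'
#' Counts are drawn per probe and sample as negative binomial with mean
#' `lane_factor * donor_factor * 2^(log2 baseline + planted effects)` and
#' size `1/dispersion` (`dispersion = 0` gives the deterministic
#' `round(mean)` limit). Lane factors are lognormal per sample and apply to
#' all probe classes including spike-ins, so they are identifiable from
#' positive controls alone. Housekeeping candidates receive no planted
#' effects and have their dispersion and donor variability scaled by
#' `hk_var_mult`, which makes reference-gene recovery testable. Spike-in
#' controls carry only technical overdispersion (`control_dispersion`).
#'
#' @param panel a `gene_panel`.
#' @param registry a `condition_registry`.
#' @param n_donors,days,include_day0,arms passed to
#'   [build_design_table()] when `design` is not supplied.
#' @param design optional pre-built `design_table`.
#' @param baseline_mean baseline expected count of measured genes (scalar,
#'   or named per-gene vector).
#' @param gene_log2_sd SD of per-gene baseline log2 offsets (0 = all genes
#'   share `baseline_mean`).
#' @param dispersion NB dispersion (reciprocal size) of measured genes.
#' @param control_dispersion technical NB dispersion of control probes.
#' @param lane_sd SD of per-sample log lane factors.
#' @param donor_sd SD of per-(gene, donor) biological log2 offsets.
#' @param hk_var_mult variance multiplier (< 1) applied to housekeeping
#'   candidates' dispersion and donor SD.
#' @param pos_scale counts per nominal concentration unit for the positive
#'   spike-in series.
#' @param neg_mean expected background count of negative control probes.
#' @param effects list of [planted_effect()]s.
#' @param day_scale named multiplier applied to planted effects per day
#'   (e.g. `c("1" = 0.5, "7" = 1)` makes day-7 effects twice day-1).
#' @param seed integer seed; the simulation is fully reproducible from
#'   (config, seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(panel, registry, n_donors = 3L, days = c(1L, 7L),
                       include_day0 = TRUE,
                       arms = c("factorial", "isoform", "density"),
                       design = NULL,
                       baseline_mean = 400, gene_log2_sd = 0,
                       dispersion = 0.05, control_dispersion = 0.005,
                       lane_sd = 0.2, donor_sd = 0.15, hk_var_mult = 0.25,
                       pos_scale = 150, neg_mean = 2,
                       effects = list(), day_scale = c("1" = 1, "7" = 1),
                       seed = 1L) {
  if (any(c(dispersion, control_dispersion, lane_sd, donor_sd) < 0)) {
    stop("variance parameters (dispersion, control_dispersion, lane_sd, ",
         "donor_sd) must be non-negative")
  }
  if (any(baseline_mean <= 0)) stop("baseline_mean must be positive")
  if (is.null(design)) {
    design <- build_design_table(registry, n_donors = n_donors, days = days,
                                 include_day0 = include_day0, arms = arms)
  }
  structure(list(panel = panel, registry = registry, design = design,
                 baseline_mean = baseline_mean, gene_log2_sd = gene_log2_sd,
                 dispersion = dispersion,
                 control_dispersion = control_dispersion,
                 lane_sd = lane_sd, donor_sd = donor_sd,
                 hk_var_mult = hk_var_mult, pos_scale = pos_scale,
                 neg_mean = neg_mean, effects = effects,
                 day_scale = day_scale, seed = as.integer(seed)),
            class = "sim_config")
}

## Which samples does a planted term reach?
term_active_samples <- function(term, days, design, registry,
                                cond = NULL) {
  if (is.null(cond)) {
    cond <- lapply(design$condition_id, lookup_condition, registry = registry)
  }
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  part_on <- function(r, part) {
    switch(part,
      TGFB  = !is.na(r$TGFB),
      TGFB1 = identical(r$TGFB, "TGFB1"),
      TGFB2 = identical(r$TGFB, "TGFB2"),
      TGFB3 = identical(r$TGFB, "TGFB3"),
      BMP   = !is.na(r$BMP),
      BMP2  = identical(r$BMP, "BMP2"),
      BMP4  = identical(r$BMP, "BMP4"),
      BMP6  = identical(r$BMP, "BMP6"),
      DEX   = isTRUE(r$DEX),
      IGF1  = isTRUE(r$IGF1),
      FGF2  = isTRUE(r$FGF2),
      day   = TRUE,
      stop("unknown planted term part: ", part)
    )
  }
  on <- vapply(cond, function(r) all(vapply(parts, part_on, logical(1), r = r)),
               logical(1))
  on & design$day %in% days
}

resolve_target <- function(target, panel) {
  if (length(target) == 1 && target %in% c("wanted", "unwanted")) {
    return(panel_symbols(panel, marker_set = target))
  }
  missing <- setdiff(target, panel$symbol)
  if (length(missing)) stop("planted target gene(s) not in panel: ",
                            paste(missing, collapse = ", "))
  target
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a digital-count screen
#'
#' @param config a [sim_config()].
#' @return list with `screen` (a `count_screen`: counts matrix with panel and
#'   design), and `truth` (a `sim_truth`: the generative per-gene log2 means
#'   per sample — biology only, before lane/donor factors — plus the planted
#'   effect list, lane log factors, donor log2 offsets and the identities of
#'   the stable housekeeping genes).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  design <- config$design
  genes <- measured_symbols(panel)
  hk <- panel_symbols(panel, cls = "housekeeping_candidate")
  n_g <- length(genes)
  n_s <- nrow(design)

  base_mean <- config$baseline_mean
  if (length(base_mean) == 1) {
    base_mean <- setNames(rep(base_mean, n_g), genes)
  } else if (!all(genes %in% names(base_mean))) {
    stop("per-gene baseline_mean must name every measured gene")
  } else {
    base_mean <- base_mean[genes]
  }

  withr::with_seed(config$seed, {
    base_log2 <- log2(base_mean) +
      if (config$gene_log2_sd > 0) rnorm(n_g, 0, config$gene_log2_sd) else 0
    names(base_log2) <- genes

    donor_sd_g <- ifelse(genes %in% hk,
                         config$donor_sd * sqrt(config$hk_var_mult),
                         config$donor_sd)
    n_donors <- max(design$donor)
    donor_off <- matrix(rnorm(n_g * n_donors, 0, donor_sd_g),
                        nrow = n_g, ncol = n_donors,
                        dimnames = list(genes, NULL))

    lane_log <- rnorm(n_s, 0, config$lane_sd)
    names(lane_log) <- design$sample_id

    ## biology-only generative log2 mean per gene x sample
    log2_bio <- matrix(base_log2, n_g, n_s,
                       dimnames = list(genes, design$sample_id))
    cond_rows <- lapply(design$condition_id, lookup_condition,
                        registry = config$registry)
    term_cache <- new.env(parent = emptyenv())
    for (ef in config$effects) {
      tgt <- resolve_target(ef$target, panel)
      if (any(tgt %in% hk)) {
        stop("planted effects may not target housekeeping candidates")
      }
      key <- paste(ef$term, paste(ef$days, collapse = "+"))
      if (is.null(term_cache[[key]])) {
        term_cache[[key]] <- term_active_samples(ef$term, ef$days, design,
                                                 config$registry, cond_rows)
      }
      on <- term_cache[[key]]
      if (!any(on)) next
      scale <- config$day_scale[as.character(design$day[on])]
      scale[is.na(scale)] <- 1
      log2_bio[tgt, on] <- log2_bio[tgt, on] +
        rep(ef$log2_effect * scale, each = length(tgt))
    }

    mu <- 2^(log2_bio + donor_off[, design$donor]) *
      rep(exp(lane_log), each = n_g)
    disp_g <- ifelse(genes %in% hk,
                     config$dispersion * config$hk_var_mult,
                     config$dispersion)
    counts_meas <- matrix(NA_real_, n_g, n_s,
                          dimnames = list(genes, design$sample_id))
    for (i in seq_len(n_g)) {
      counts_meas[i, ] <- nb_draw(n_s, mu[i, ], disp_g[i])
    }

    pos_inputs <- attr(panel, "pos_inputs")
    pos_mu <- outer(pos_inputs * config$pos_scale, exp(lane_log))
    neg_syms <- panel_symbols(panel, cls = "negative_ctrl")
    neg_mu <- matrix(config$neg_mean, length(neg_syms), n_s,
                     dimnames = list(neg_syms, design$sample_id)) *
      rep(exp(lane_log), each = length(neg_syms))
    pos_counts <- matrix(nb_draw(length(pos_mu), pos_mu,
                                 config$control_dispersion),
                         nrow(pos_mu), dimnames = dimnames(pos_mu))
    neg_counts <- matrix(nb_draw(length(neg_mu), neg_mu,
                                 config$control_dispersion),
                         nrow(neg_mu), dimnames = dimnames(neg_mu))
  })

  counts <- rbind(counts_meas, pos_counts, neg_counts)
  counts <- counts[panel$symbol, , drop = FALSE]
  storage.mode(counts) <- "integer"

  screen <- new_count_screen(counts, panel, design)
  truth <- structure(list(log2_mean = log2_bio, effects = config$effects,
                          lane_log = lane_log, donor_log2 = donor_off,
                          baseline_log2 = base_log2,
                          housekeeping = hk, seed = config$seed),
                     class = "sim_truth")
  list(screen = screen, truth = truth)
}

#' Simulate a null screen
#'
#' As [simulate_counts()] with the planted-effect list forced empty; lane
#' and donor variation are retained. Used for type-I-error and FDR
#' calibration of the downstream tests.
#'
#' @param config a [sim_config()].
#' @return as [simulate_counts()].
#' @export
simulate_null_screen <- function(config) {
  config$effects <- list()
  simulate_counts(config)
}

## ---- presets -------------------------------------------------------------

## Deterministic per-gene effect spread for a marker set: multipliers
## centred on 1 so the set-average planted effect equals the nominal value.
set_effects <- function(symbols, term, log2_effect, mult_range = c(0.6, 1.4),
                        days = c(1, 7)) {
  mult <- seq(mult_range[1], mult_range[2], length.out = length(symbols))
  Map(function(sym, m) planted_effect(sym, term, log2_effect * m, days),
      symbols, mult)
}

block_effects <- function(symbols, term, magnitudes) {
  Map(function(sym, e) planted_effect(sym, term, e), symbols, magnitudes)
}

#' Simulation presets
#'
#' `paper_like_config()` plants the qualitative structure reported for this
#' kind of chondrogenesis screen: positive TGFβ (any isoform), DEX and BMP
#' effects on the wanted markers with a positive TGFβ×DEX synergy and a
#' damping TGFβ×BMP interaction; TGFβ- and BMP-driven unwanted-marker
#' induction that DEX and the TGFβ×BMP interaction cancel in the best
#' conditions; a negative FGF2 effect; an exactly null IGF1; a strong
#' TGFβ-specific COL10A1 induction; a BGLAP-like gene downregulated by DEX
#' in every condition; blocks of filler genes responding to single factors
#' (many for TGFβ and DEX, few for BMP); day-7 effects twice the day-1
#' effects. `null_config()` keeps the same noise model with no effects.
#'
#' @param panel gene panel (default [build_default_panel()]).
#' @param registry condition registry (default [build_condition_registry()]).
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`. The BGLAP/MMP1 analog filler symbols chosen are
#'   recorded in `attr(, "analogs")`.
#' @export
paper_like_config <- function(panel = build_default_panel(),
                              registry = build_condition_registry(),
                              seed = 1L, ...) {
  filler <- setdiff(panel_symbols(panel, cls = "endogenous",
                                  marker_set = "other"), character(0))
  need <- 104
  if (length(filler) < need) {
    stop("paper-like preset needs at least ", need, " filler genes; ",
         "use a larger panel")
  }
  take <- function(n) {
    out <- filler[seq_len(n)]
    filler <<- filler[-seq_len(n)]
    out
  }
  bglap_analog <- take(1)
  mmp1_analog <- take(1)
  tgfb_blk <- take(30)
  dex_blk <- take(30)
  syn_blk <- take(10)
  bmp_blk <- take(6)
  fgf_blk <- take(6)
  day_blk <- take(20)

  wanted <- panel_symbols(panel, marker_set = "wanted")
  unwanted <- panel_symbols(panel, marker_set = "unwanted")

  effects <- c(
    ## wanted marker set: mains, synergy and damping
    set_effects(wanted, "TGFB", 1.5),
    set_effects(wanted, "DEX", 0.5),
    set_effects(wanted, "BMP", 0.8),
    set_effects(wanted, "FGF2", -0.8),
    set_effects(wanted, "TGFB:DEX", 1.0),
    set_effects(wanted, "TGFB:BMP", -0.5),
    ## unwanted marker set: induced by TGFB/BMP, cancelled by DEX and the
    ## TGFB x BMP interaction in the combined conditions
    set_effects(unwanted, "TGFB", 0.8, c(0.7, 1.3)),
    set_effects(unwanted, "BMP", 0.6, c(0.7, 1.3)),
    set_effects(unwanted, "TGFB:DEX", -0.8, c(0.7, 1.3)),
    set_effects(unwanted, "TGFB:BMP", -0.6, c(0.7, 1.3)),
    set_effects(unwanted, "FGF2", -0.3, c(0.7, 1.3)),
    ## named single-gene stories
    list(planted_effect("COL10A1", "TGFB", 1.2),
         planted_effect(bglap_analog, "DEX", -2.0),
         planted_effect(mmp1_analog, "DEX", -1.5)),
    ## filler blocks: many TGFB- and DEX-responsive genes, few BMP ones
    block_effects(tgfb_blk, "TGFB",
                  c(seq(0.8, 2.4, length.out = 18),
                    seq(-0.8, -2.0, length.out = 12))),
    block_effects(dex_blk, "DEX",
                  c(seq(0.8, 2.2, length.out = 16),
                    seq(-0.8, -2.2, length.out = 14))),
    block_effects(syn_blk, "TGFB:DEX",
                  c(seq(1.0, 1.6, length.out = 5),
                    seq(-1.0, -1.6, length.out = 5))),
    block_effects(bmp_blk, "BMP", c(1.2, 1.5, 1.8, -1.2, -1.5, -1.8)),
    block_effects(fgf_blk, "FGF2", c(-1.0, -1.3, -1.6, -1.9, 0.9, 1.2)),
    ## time-in-culture program shared by all treated samples
    block_effects(day_blk, "day",
                  c(seq(0.5, 1.5, length.out = 10),
                    seq(-0.5, -1.5, length.out = 10)))
  )
  names(effects) <- NULL

  cfg <- sim_config(panel, registry, effects = effects,
                    gene_log2_sd = 1.5,
                    day_scale = c("1" = 0.5, "7" = 1),
                    seed = seed, ...)
  attr(cfg, "analogs") <- c(BGLAP = bglap_analog, MMP1 = mmp1_analog)
  cfg
}

#' @rdname paper_like_config
#' @export
null_config <- function(panel = build_default_panel(),
                        registry = build_condition_registry(),
                        seed = 1L, ...) {
  sim_config(panel, registry, effects = list(), gene_log2_sd = 1.5,
             seed = seed, ...)
}
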