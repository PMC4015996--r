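## Configuration validation and the end-to-end screen pipeline.

CONFIG_DEFAULTS <- list(
  preset = "paper_like",     # paper_like | null (ignored when counts_dir set)
  counts_dir = NULL,         # read counts from here instead of simulating
  dialect = "rcc_like",
  registry_file = NULL,      # condition-numbering override (TSV)
  n_genes = 364L,
  n_donors = 3L,
  days = c(1L, 7L),
  alpha = 0.05,
  fc_threshold = 1,
  fdr = 0.05,
  n_refs = 5L,
  offset_policy = "negctrl",
  group_by = "day",
  pseudo_count = 0.5,
  seed = 1L
)

## Detect duplicated top-level YAML keys (silent last-wins would hide
## configuration mistakes).
check_duplicate_keys <- function(path) {
  lines <- readLines(path)
  keyed <- grep("^[A-Za-z_][A-Za-z0-9_]*:", lines)
  key_names <- sub(":.*$", "", lines[keyed])
  dup <- duplicated(key_names)
  if (any(dup)) {
    stop("duplicate config key '", key_names[dup][1], "' at line ",
         keyed[dup][1])
  }
}

#' Validate a run configuration
#'
#' Fills defaults (alpha 0.05, twofold cut-off, FDR 0.05, 5 reference
#' genes), rejects unknown keys, out-of-range thresholds and duplicated
#' YAML keys.
#'
#' @param raw a YAML file path or a named list (empty input gives the full
#'   default configuration).
#' @return a `run_config` list.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) {
    check_duplicate_keys(raw)
    raw <- yaml::read_yaml(raw)
    if (is.null(raw)) raw <- list()
  }
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw, keep.null = TRUE)
  for (key in c("alpha", "fdr")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0 || cfg[[key]] >= 1) {
      stop(key, " must lie in (0, 1); got ", cfg[[key]])
    }
  }
  if (cfg$fc_threshold <= 0) stop("fc_threshold must be > 0")
  if (cfg$n_refs < 2) stop("n_refs must be >= 2")
  if (!cfg$preset %in% c("paper_like", "null")) {
    stop("preset must be 'paper_like' or 'null'")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

## Tiny stable rolling hash of the configuration for provenance.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full screen pipeline
#'
#' Simulation (or reading) of counts, normalization, per-day marker scoring
#' with the day-1 vs day-7 rank correlation, factorial effect inference on
#' the wanted and unwanted responses, the key-condition contrast battery
#' with overlaps, per-factor uniform gene sets, condition enrichment
#' ranking, and PCA views. Fully deterministic for a given seed.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @return a `report_bundle` list with all stage outputs and a `provenance`
#'   record (seed, parameters, chosen references, config hash).
#' @export
run_screen <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  registry <- if (!is.null(config$registry_file)) {
    read_registry(config$registry_file)
  } else {
    build_condition_registry()
  }

  if (!is.null(config$counts_dir)) {
    screen <- read_counts(config$counts_dir, dialect = config$dialect)
    truth <- NULL
  } else {
    panel <- build_default_panel(config$n_genes, seed = config$seed)
    sim_cfg <- if (config$preset == "paper_like") {
      paper_like_config(panel, registry, seed = config$seed,
                        n_donors = config$n_donors, days = config$days)
    } else {
      null_config(panel, registry, seed = config$seed,
                  n_donors = config$n_donors, days = config$days)
    }
    sim <- simulate_counts(sim_cfg)
    screen <- sim$screen
    truth <- sim$truth
  }

  expr <- normalize_screen(screen, n_refs = config$n_refs,
                           group_by = config$group_by,
                           offset_policy = config$offset_policy,
                           pseudo_count = config$pseudo_count)

  days_present <- setdiff(sort(unique(expr$design$day)), 0L)
  fact_ids <- registry$id[registry$arm == "factorial"]
  ## condition ranking over the factorial arm (the screen's comparison set);
  ## scores_all additionally covers the isoform/density arms
  scores <- lapply(setNames(days_present, paste0("day", days_present)),
                   function(d) {
                     marker_scores(studentize(expr, day = d,
                                              conditions = fact_ids),
                                   expr$panel)
                   })
  scores_all <- lapply(setNames(days_present, paste0("day", days_present)),
                       function(d) {
                         marker_scores(studentize(expr, day = d), expr$panel)
                       })
  rank_cor <- if (all(c(1, 7) %in% days_present)) {
    rank_correlation(scores$day1, scores$day7)
  } else NULL

  effects <- lapply(setNames(days_present, paste0("day", days_present)),
                    function(d) {
    resp <- marker_responses(expr, registry, day = d, arms = "factorial")
    list(wanted = test_effects(estimate_effects(resp, registry, "wanted"),
                               alpha = config$alpha),
         unwanted = test_effects(estimate_effects(resp, registry, "unwanted"),
                                 alpha = config$alpha))
  })

  de_day <- max(days_present)
  key_pairs <- list(dex_to_tgfb = c(12L, 16L),
                    dex_to_tgfb_bmp = c(11L, 15L),
                    bmp_to_tgfb = c(15L, 16L),
                    bmp_to_tgfb_dex = c(11L, 12L))
  key_contrasts <- lapply(key_pairs, function(p) {
    de_contrast(expr, p[1], p[2], day = de_day,
                fc_threshold = config$fc_threshold,
                q_threshold = config$fdr)
  })
  overlaps <- list(
    dex = contrast_overlap(key_contrasts$dex_to_tgfb,
                           key_contrasts$dex_to_tgfb_bmp),
    bmp = contrast_overlap(key_contrasts$bmp_to_tgfb,
                           key_contrasts$bmp_to_tgfb_dex)
  )
  uniform <- lapply(setNames(SCREEN_FACTORS, SCREEN_FACTORS), function(f) {
    uniform_factor_genes(expr, registry, f, day = de_day,
                         fc_threshold = config$fc_threshold,
                         q_threshold = config$fdr)
  })

  enrichment <- enrichment_table(expr, registry, day = de_day,
                                 fdr = config$fdr)
  pca_all <- pca_screen(expr)
  pca_factorial <- pca_screen(
    expr, day = c(0L, de_day),
    conditions = c(UNTREATED_ID, registry$id[registry$arm == "factorial"]))

  structure(list(
    config = config,
    registry = registry,
    screen = screen,
    truth = truth,
    expr = expr,
    scores = scores,
    scores_all = scores_all,
    rank_correlation = rank_cor,
    effects = effects,
    key_contrasts = key_contrasts,
    overlaps = overlaps,
    uniform = uniform,
    enrichment = enrichment,
    pca = list(all = pca_all, factorial = pca_factorial),
    provenance = list(seed = config$seed,
                      config = unclass(config),
                      config_hash = config_hash(config),
                      reference_genes = expr$params$reference_genes,
                      glog_c = expr$params$glog_c)
  ), class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' Emits the machine-readable stage outputs as TSV/JSON: normalized
#' expression, per-day marker scores, effect tables with normal-plot
#' coordinates, key-contrast DE tables, uniform gene sets, enrichment
#' table, PCA scores/loadings/variance, and the provenance record.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  expr_df <- data.frame(symbol = rownames(bundle$expr$expr),
                        bundle$expr$expr, check.names = FALSE)
  w(expr_df, "expression.tsv")
  for (d in names(bundle$scores)) w(bundle$scores[[d]],
                                    paste0("scores_", d, ".tsv"))
  for (d in names(bundle$effects)) {
    for (resp in names(bundle$effects[[d]])) {
      tab <- bundle$effects[[d]][[resp]]
      w(tab, paste0("effects_", d, "_", resp, ".tsv"))
      w(attr(tab, "normal_plot"),
        paste0("normalplot_", d, "_", resp, ".tsv"))
    }
  }
  for (k in names(bundle$key_contrasts)) {
    w(bundle$key_contrasts[[k]], paste0("contrast_", k, ".tsv"))
  }
  w(bundle$enrichment, "enrichment.tsv")
  w(bundle$pca$all$scores, "pca_scores.tsv")
  w(data.frame(component = seq_along(bundle$pca$all$var_explained),
               var_explained = bundle$pca$all$var_explained),
    "pca_variance.tsv")
  jsonlite::write_json(
    list(rank_correlation = bundle$rank_correlation,
         overlaps = lapply(bundle$overlaps, function(o) {
           o[c("n_a", "n_b", "n_overlap")]
         }),
         uniform_counts = lapply(bundle$uniform, function(u) {
           list(up = length(u$up), down = length(u$down))
         }),
         provenance = bundle$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(dir)
}
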