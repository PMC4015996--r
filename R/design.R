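## Screening design: 2^5 factorial arm, isoform and density arms, condition
## numbering, sample design table, coded model matrices.

#' The five screened factors, in display order
#' @export
SCREEN_FACTORS <- c("TGFB1", "DEX", "BMP2", "IGF1", "FGF2")

## Weights of the canonical condition-numbering rule
## id = 32 - (16*TGFB1 + 8*FGF2 + 4*DEX + 2*IGF1 + 1*BMP2).
## This is the unique weighting consistent with every numbered condition
## anchor in the study design (e.g. 32 = no factors, 16 = TGFB1 alone,
## 11 vs 12 differ only in BMP2, 9 vs 11 only in IGF1).
CONDITION_WEIGHTS <- c(TGFB1 = 16, FGF2 = 8, DEX = 4, IGF1 = 2, BMP2 = 1)

#' Reserved pseudo-condition id for day-0 untreated cells
#' @export
UNTREATED_ID <- 0L

#' Enumerate a two-level full factorial design
#'
#' All 2^k on/off combinations in standard (Yates) order: the first factor
#' alternates fastest, the first run is all-off and the last all-on.
#'
#' @param k number of factors, 1..10.
#' @return a 2^k x k integer matrix of 0/1 levels.
#' @examples
#' enumerate_factorial(2)
#' @export
enumerate_factorial <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 10 || k != round(k)) {
    stop("k must be a single integer in 1..10")
  }
  k <- as.integer(k)
  m <- sapply(seq_len(k), function(j) rep(rep(0:1, each = 2^(j - 1)),
                                          length.out = 2^k))
  matrix(as.integer(m), nrow = 2^k, ncol = k,
         dimnames = list(NULL, paste0("F", seq_len(k))))
}

## id <-> factor-presence bijection for the factorial arm (ids 1..32)
factorial_id_from_presence <- function(presence) {
  ## presence: named logical/0-1 over SCREEN_FACTORS
  32L - as.integer(sum(CONDITION_WEIGHTS[names(CONDITION_WEIGHTS)] *
                         as.integer(presence[names(CONDITION_WEIGHTS)])))
}

presence_from_factorial_id <- function(id) {
  stopifnot(id >= 1, id <= 32)
  m <- 32L - as.integer(id)
  out <- setNames(bitwAnd(m, CONDITION_WEIGHTS) > 0, names(CONDITION_WEIGHTS))
  out[SCREEN_FACTORS]
}

#' Build the 48-condition registry
#'
#' Conditions 1..32 form the full 2^5 factorial arm (TGFβ1, DEX, BMP2, IGF1,
#' FGF2 present or absent at 1e7 cells/mL), numbered by the canonical rule
#' id = 32 − (16·TGFβ1 + 8·FGF2 + 4·DEX + 2·IGF1 + 1·BMP2), so condition 32
#' is the no-factor baseline medium and condition 16 is TGFβ1 alone.
#' Conditions 33..48 are the isoform/density arms: TGFβ2 and TGFβ3 each
#' alone / +DEX / +DEX+BMP2 (33–38); BMP4 and BMP6 each alone / +TGFβ1 /
#' +TGFβ1+DEX (39–44); and seeding densities 1.25, 2.5, 5, 20 ×1e6 cells/mL
#' under TGFβ1+DEX+BMP2 (45–48), completing the log2-spaced density series
#' around the factorial-arm density of 1e7.
#'
#' @param extra_conditions optional data.frame overriding rows 33..48 (same
#'   columns as the returned registry), for users with a different
#'   arm layout.
#' @return a `condition_registry` data.frame with columns `id`, `arm`
#'   (factorial/isoform/density), `TGFB` (NA, "TGFB1", "TGFB2", "TGFB3"),
#'   `BMP` (NA, "BMP2", "BMP4", "BMP6"), `DEX`, `IGF1`, `FGF2` (logical) and
#'   `density` (cells/mL).
#' @export
build_condition_registry <- function(extra_conditions = NULL) {
  fact <- do.call(rbind, lapply(1:32, function(id) {
    p <- presence_from_factorial_id(id)
    data.frame(id = id, arm = "factorial",
               TGFB = if (p[["TGFB1"]]) "TGFB1" else NA_character_,
               BMP = if (p[["BMP2"]]) "BMP2" else NA_character_,
               DEX = p[["DEX"]], IGF1 = p[["IGF1"]], FGF2 = p[["FGF2"]],
               density = 1e7, stringsAsFactors = FALSE)
  }))
  if (is.null(extra_conditions)) {
    iso_row <- function(id, tgfb, bmp, dex, arm, density = 1e7) {
      data.frame(id = id, arm = arm, TGFB = tgfb, BMP = bmp, DEX = dex,
                 IGF1 = FALSE, FGF2 = FALSE, density = density,
                 stringsAsFactors = FALSE)
    }
    tgfb_iso <- do.call(rbind, Map(
      iso_row, 33:38,
      tgfb = rep(c("TGFB2", "TGFB3"), each = 3),
      bmp = rep(c(NA, NA, "BMP2"), 2),
      dex = rep(c(FALSE, TRUE, TRUE), 2),
      arm = "isoform"))
    bmp_iso <- do.call(rbind, Map(
      iso_row, 39:44,
      tgfb = rep(c(NA, "TGFB1", "TGFB1"), 2),
      bmp = rep(c("BMP4", "BMP6"), each = 3),
      dex = rep(c(FALSE, FALSE, TRUE), 2),
      arm = "isoform"))
    dens <- do.call(rbind, Map(
      iso_row, 45:48, tgfb = "TGFB1", bmp = "BMP2", dex = TRUE,
      arm = "density", density = c(1.25e6, 2.5e6, 5e6, 2e7)))
    extra_conditions <- rbind(tgfb_iso, bmp_iso, dens)
  }
  reg <- rbind(fact, extra_conditions)
  rownames(reg) <- NULL
  stopifnot(!anyDuplicated(reg$id))
  class(reg) <- c("condition_registry", "data.frame")
  reg
}

#' Look up one condition
#'
#' @param registry a `condition_registry`.
#' @param id condition id (the reserved untreated id 0 returns an all-absent
#'   row).
#' @return a one-row data.frame.
#' @export
lookup_condition <- function(registry, id) {
  if (id == UNTREATED_ID) {
    return(data.frame(id = UNTREATED_ID, arm = "untreated",
                      TGFB = NA_character_, BMP = NA_character_,
                      DEX = FALSE, IGF1 = FALSE, FGF2 = FALSE,
                      density = 1e7, stringsAsFactors = FALSE))
  }
  row <- registry[registry$id == id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown condition id: ", id)
  row
}

#' Factor presence indicators for conditions
#'
#' Canonical-factor presence for each requested condition. Isoform levels
#' count as presence of their family factor only when `strict = FALSE`
#' (e.g. TGFB2 present => TGFB1 column TRUE); with `strict = TRUE` (default)
#' only the factorial-arm levels TGFB1/BMP2 count.
#'
#' @param registry a `condition_registry`.
#' @param ids condition ids.
#' @param strict see above.
#' @return logical matrix length(ids) x 5 with columns `SCREEN_FACTORS`.
#' @export
condition_presence <- function(registry, ids, strict = TRUE) {
  rows <- lapply(ids, lookup_condition, registry = registry)
  out <- t(vapply(rows, function(r) {
    tg <- if (strict) identical(r$TGFB, "TGFB1") else !is.na(r$TGFB)
    bm <- if (strict) identical(r$BMP, "BMP2") else !is.na(r$BMP)
    c(TGFB1 = tg, DEX = r$DEX, BMP2 = bm, IGF1 = r$IGF1, FGF2 = r$FGF2)
  }, logical(5)))
  rownames(out) <- ids
  out
}

#' Build a sample design table
#'
#' One sample per (condition, donor, day), plus one untreated day-0 sample
#' per donor; each sample gets its own lane.
#'
#' @param registry a `condition_registry`.
#' @param n_donors number of donors.
#' @param days assay days (subset of c(1, 7)).
#' @param include_day0 add untreated day-0 samples (reserved condition 0).
#' @param arms restrict to these arms (default all).
#' @return a `design_table` data.frame with columns `sample_id`,
#'   `condition_id`, `donor`, `day`, `lane`.
#' @export
build_design_table <- function(registry, n_donors = 3L, days = c(1L, 7L),
                               include_day0 = TRUE,
                               arms = c("factorial", "isoform", "density")) {
  ids <- registry$id[registry$arm %in% arms]
  grid <- expand.grid(condition_id = ids, donor = seq_len(n_donors),
                      day = days, KEEP.OUT.ATTRS = FALSE)
  if (include_day0) {
    grid <- rbind(data.frame(condition_id = UNTREATED_ID,
                             donor = seq_len(n_donors), day = 0L),
                  grid)
  }
  grid <- grid[order(grid$day, grid$condition_id, grid$donor), ]
  design <- data.frame(
    sample_id = sprintf("d%d_c%02d_don%d", grid$day, grid$condition_id,
                        grid$donor),
    condition_id = grid$condition_id,
    donor = grid$donor,
    day = grid$day,
    lane = seq_len(nrow(grid)),
    stringsAsFactors = FALSE
  )
  rownames(design) <- NULL
  stopifnot(!anyDuplicated(design[c("condition_id", "donor", "day")]))
  class(design) <- c("design_table", "data.frame")
  design
}

factorial_term_names <- function(max_order = 3L) {
  terms <- SCREEN_FACTORS
  orders <- rep(1L, 5)
  for (ord in 2:3) {
    if (max_order >= ord) {
      combos <- utils::combn(SCREEN_FACTORS, ord,
                             FUN = paste, collapse = ":")
      terms <- c(terms, combos)
      orders <- c(orders, rep(ord, length(combos)))
    }
  }
  data.frame(term = terms, order = orders, stringsAsFactors = FALSE)
}

#' Encode the coded factorial model matrix
#'
#' Builds the ±1-coded design matrix for factorial inference: intercept,
#' the five main-effect columns (+1 = factor present), all interaction
#' product columns up to `max_order`, and donor block indicator columns
#' (treatment coding against donor 1). Interaction columns are element-wise
#' products of main-effect columns, so all effect columns are mutually
#' orthogonal over a complete replicate.
#'
#' @param design a `design_table` restricted to factorial-arm samples.
#' @param registry a `condition_registry`.
#' @param max_order highest interaction order to encode (1, 2 or 3).
#' @return list with `X` (model matrix), `terms` (data.frame term/order),
#'   `effect_cols` and `donor_cols` (column names).
#' @export
encode_model_matrix <- function(design, registry, max_order = 3L) {
  if (!max_order %in% 1:3) stop("max_order must be 1, 2 or 3")
  arm <- registry$arm[match(design$condition_id, registry$id)]
  if (any(is.na(arm)) || any(arm != "factorial")) {
    stop("design contains non-factorial conditions; ",
         "restrict to the factorial arm first")
  }
  pres <- condition_presence(registry, design$condition_id)
  main <- 2 * pres - 1     # coded -1/+1
  storage.mode(main) <- "double"
  terms <- factorial_term_names(max_order)
  eff <- matrix(NA_real_, nrow(design), nrow(terms),
                dimnames = list(design$sample_id, terms$term))
  for (j in seq_len(nrow(terms))) {
    parts <- strsplit(terms$term[j], ":", fixed = TRUE)[[1]]
    eff[, j] <- apply(main[, parts, drop = FALSE], 1, prod)
  }
  donor <- factor(design$donor)
  donor_cols <- character(0)
  dmat <- NULL
  if (nlevels(donor) > 1) {
    dmat <- model.matrix(~donor)[, -1, drop = FALSE]
    donor_cols <- colnames(dmat)
  }
  X <- cbind(`(Intercept)` = 1, dmat, eff)
  rownames(X) <- design$sample_id
  list(X = X, terms = terms, effect_cols = terms$term, donor_cols = donor_cols)
}

#' Write / read the condition registry and design table as TSV
#' @param registry a `condition_registry`; @param design a `design_table`.
#' @param path file path.
#' @export
write_registry <- function(registry, path) {
  write.table(as.data.frame(registry), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  reg <- read.delim(path, stringsAsFactors = FALSE)
  reg$TGFB <- as.character(reg$TGFB)
  reg$BMP <- as.character(reg$BMP)
  class(reg) <- c("condition_registry", "data.frame")
  reg
}

#' @rdname write_registry
#' @export
write_design <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_design <- function(path) {
  design <- read.delim(path, stringsAsFactors = FALSE)
  class(design) <- c("design_table", "data.frame")
  design
}
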