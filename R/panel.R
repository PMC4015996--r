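## Gene panel: marker sets, housekeeping candidates, control probes.

#' Wanted (hyaline cartilage ECM) marker symbols
#'
#' The 14 genes of the "wanted" marker set: extracellular-matrix molecules
#' that are hallmarks of native hyaline cartilage (slash entries such as
#' COL11A1/2 expanded to individual symbols).
#' @export
WANTED_MARKERS <- c(
  "ACAN", "BGN", "COL11A1", "COL11A2", "COL2A1",
  "COL9A1", "COL9A2", "COL9A3", "COMP", "DCN",
  "FMOD", "HAPLN1", "LUM", "MATN3"
)

#' Unwanted (hypertrophy / bone / fat / fibrocartilage) marker symbols
#'
#' The 11 genes of the "unwanted" marker set: molecules distinctive for
#' hypertrophic or fibrous cartilage and master regulators of osteogenic or
#' adipogenic differentiation.
#' @export
UNWANTED_MARKERS <- c(
  "ALPL", "COL10A1", "COL1A1", "COL1A2", "COL3A1",
  "OGN", "PPARG", "RUNX2", "SP7", "SPP1", "VCAN"
)

## Candidate endogenous reference genes offered to the stability ranking.
HOUSEKEEPING_CANDIDATES <- c(
  "GAPDH", "ACTB", "B2M", "RPLP0", "TBP",
  "GUSB", "HPRT1", "PGK1", "PPIA", "TUBB"
)

## Spike-in positive control series: strictly decreasing geometric series of
## nominal input concentrations (arbitrary units, ratio 4), plus negative
## control probes with no target.
POSITIVE_CTRL_INPUTS <- c(
  POS_A = 128, POS_B = 32, POS_C = 8,
  POS_D = 2, POS_E = 0.5, POS_F = 0.125
)
NEGATIVE_CTRL_PROBES <- paste0("NEG_", LETTERS[1:8])

#' Build the default gene panel
#'
#' Constructs a gene panel of `n_genes` measured genes: the 14 wanted and 11
#' unwanted marker genes, up to 10 named housekeeping candidates, and
#' synthetic filler symbols (`GENE0001`, ...) up to `n_genes`; plus the fixed
#' positive spike-in control series and negative control probes. Filler
#' symbols are deliberately synthetic so they can never collide with marker
#' logic. The default size of 364 matches a custom chondrogenesis panel.
#'
#' @param n_genes number of measured (non-control) genes; at least 25 so the
#'   full marker sets fit.
#' @param seed integer seed controlling filler symbol generation (markers,
#'   housekeeping candidates and control probes are fixed).
#' @return an object of class `gene_panel`: a data.frame with columns
#'   `symbol`, `cls` (one of endogenous, housekeeping_candidate,
#'   positive_ctrl, negative_ctrl) and `marker_set` (wanted, unwanted,
#'   other), with the positive-control input series in
#'   `attr(, "pos_inputs")`.
#' @examples
#' panel <- build_default_panel()
#' table(panel$cls)
#' @export
build_default_panel <- function(n_genes = 364L, seed = 1L) {
  n_min <- length(WANTED_MARKERS) + length(UNWANTED_MARKERS)
  if (n_genes < n_min) {
    stop("n_genes must be at least ", n_min,
         " to fit the wanted and unwanted marker sets (got ", n_genes, ")")
  }
  markers <- data.frame(
    symbol = c(WANTED_MARKERS, UNWANTED_MARKERS),
    cls = "endogenous",
    marker_set = c(rep("wanted", length(WANTED_MARKERS)),
                   rep("unwanted", length(UNWANTED_MARKERS))),
    stringsAsFactors = FALSE
  )
  n_extra <- n_genes - n_min
  hk <- head(HOUSEKEEPING_CANDIDATES, min(n_extra, length(HOUSEKEEPING_CANDIDATES)))
  n_filler <- n_extra - length(hk)
  filler <- character(0)
  if (n_filler > 0) {
    ## deterministic per seed: a shuffled pool of synthetic symbols
    pool <- sprintf("GENE%04d", seq_len(max(2L * n_filler, 50L)))
    filler <- withr::with_seed(seed, sample(pool, n_filler))
  }
  genes <- rbind(
    markers,
    if (length(hk)) data.frame(symbol = hk, cls = "housekeeping_candidate",
                               marker_set = "other", stringsAsFactors = FALSE),
    if (length(filler)) data.frame(symbol = filler, cls = "endogenous",
                                   marker_set = "other", stringsAsFactors = FALSE)
  )
  ctrls <- data.frame(
    symbol = c(names(POSITIVE_CTRL_INPUTS), NEGATIVE_CTRL_PROBES),
    cls = c(rep("positive_ctrl", length(POSITIVE_CTRL_INPUTS)),
            rep("negative_ctrl", length(NEGATIVE_CTRL_PROBES))),
    marker_set = "other",
    stringsAsFactors = FALSE
  )
  panel <- rbind(genes, ctrls)
  rownames(panel) <- NULL
  stopifnot(!anyDuplicated(panel$symbol))
  attr(panel, "pos_inputs") <- POSITIVE_CTRL_INPUTS
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Panel symbols by class or marker set
#'
#' @param panel a `gene_panel`.
#' @param cls optional class filter.
#' @param marker_set optional marker-set filter.
#' @return character vector of symbols.
#' @export
panel_symbols <- function(panel, cls = NULL, marker_set = NULL) {
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(cls)) keep <- keep & panel$cls %in% cls
  if (!is.null(marker_set)) keep <- keep & panel$marker_set %in% marker_set
  panel$symbol[keep]
}

## Measured genes = everything that is not a control probe.
measured_symbols <- function(panel) {
  panel_symbols(panel, cls = c("endogenous", "housekeeping_candidate"))
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel:", sum(x$cls %in% c("endogenous", "housekeeping_candidate")),
      "measured genes (", sum(x$marker_set == "wanted"), "wanted,",
      sum(x$marker_set == "unwanted"), "unwanted,",
      sum(x$cls == "housekeeping_candidate"), "housekeeping candidates ),",
      sum(x$cls == "positive_ctrl"), "positive and",
      sum(x$cls == "negative_ctrl"), "negative control probes\n")
  invisible(x)
}

#' Write / read a gene panel as TSV
#'
#' The TSV has columns symbol, cls, marker_set and, for positive controls,
#' pos_input (nominal input concentration).
#' @param panel a `gene_panel`.
#' @param path file path.
#' @return `read_panel` returns a `gene_panel`.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$pos_input <- attr(panel, "pos_inputs")[df$symbol]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  pos <- df$pos_input[df$cls == "positive_ctrl"]
  names(pos) <- df$symbol[df$cls == "positive_ctrl"]
  df$pos_input <- NULL
  attr(df, "pos_inputs") <- pos
  class(df) <- c("gene_panel", "data.frame")
  df
}
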