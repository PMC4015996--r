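## Count-screen container and serialization: an RCC-like per-sample CSV
## dialect and a plain genes x samples TSV with sidecar annotation tables.

CLS_TO_CODE <- c(endogenous = "Endogenous",
                 housekeeping_candidate = "Housekeeping",
                 positive_ctrl = "Positive",
                 negative_ctrl = "Negative")
CODE_TO_CLS <- setNames(names(CLS_TO_CODE), CLS_TO_CODE)

#' Construct a count screen
#'
#' Bundles a genes x samples non-negative integer count matrix with its gene
#' panel and sample design table.
#'
#' @param counts integer matrix, rownames = panel symbols, colnames =
#'   design sample ids.
#' @param panel a `gene_panel`.
#' @param design a `design_table`.
#' @return a `count_screen` list with elements `counts`, `panel`, `design`.
#' @export
new_count_screen <- function(counts, panel, design) {
  if (!all(rownames(counts) == panel$symbol)) {
    stop("count matrix rows must match the panel symbols, in order")
  }
  if (!all(colnames(counts) == design$sample_id)) {
    stop("count matrix columns must match the design sample ids, in order")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative or non-integer count for gene ",
         rownames(counts)[bad[1, 1]], " in sample ",
         colnames(counts)[bad[1, 2]])
  }
  structure(list(counts = counts, panel = panel, design = design),
            class = "count_screen")
}

#' @export
print.count_screen <- function(x, ...) {
  cat("Count screen:", nrow(x$counts), "probes x", ncol(x$counts),
      "samples;", length(unique(x$design$condition_id)), "conditions,",
      length(unique(x$design$donor)), "donors, days",
      paste(sort(unique(x$design$day)), collapse = "/"), "\n")
  invisible(x)
}

#' Write a count screen
#'
#' `dialect = "rcc_like"` writes one CSV per sample into directory `path`:
#' a header block (`Sample,<id>` / `Lane,<n>` / condition, donor, day
#' attributes) followed by `class,symbol,count` rows with class in
#' Endogenous / Housekeeping / Positive / Negative. `dialect = "tsv"` writes
#' `counts.tsv` (genes x samples), `panel.tsv` and `design.tsv` into `path`.
#'
#' @param screen a `count_screen`.
#' @param path output directory (created if needed).
#' @param dialect "rcc_like" or "tsv".
#' @return `path`, invisibly.
#' @export
write_counts <- function(screen, path, dialect = c("rcc_like", "tsv")) {
  dialect <- match.arg(dialect)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (dialect == "tsv") {
    counts <- data.frame(symbol = rownames(screen$counts),
                         screen$counts, check.names = FALSE)
    write.table(counts, file.path(path, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_panel(screen$panel, file.path(path, "panel.tsv"))
    write_design(screen$design, file.path(path, "design.tsv"))
  } else {
    codes <- CLS_TO_CODE[screen$panel$cls]
    for (j in seq_len(ncol(screen$counts))) {
      s <- screen$design[j, ]
      con <- file(file.path(path, paste0(s$sample_id, ".csv")), "w")
      writeLines(c(paste0("Sample,", s$sample_id),
                   paste0("Lane,", s$lane),
                   paste0("Condition,", s$condition_id),
                   paste0("Donor,", s$donor),
                   paste0("Day,", s$day),
                   "CodeClass,Name,Count"), con)
      writeLines(paste(codes, screen$panel$symbol, screen$counts[, j],
                       sep = ","), con)
      close(con)
    }
    write_panel(screen$panel, file.path(path, "panel.tsv"))
  }
  invisible(path)
}

read_rcc_sample <- function(file) {
  lines <- readLines(file)
  hdr_end <- match("CodeClass,Name,Count", lines)
  if (is.na(hdr_end)) stop("missing CodeClass,Name,Count header in ", file)
  hdr <- strsplit(lines[seq_len(hdr_end - 1)], ",", fixed = TRUE)
  meta <- setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  body <- read.csv(text = lines[(hdr_end):length(lines)],
                   stringsAsFactors = FALSE)
  unknown <- setdiff(unique(body$CodeClass), names(CODE_TO_CLS))
  if (length(unknown)) {
    stop("unknown gene class code(s) in ", basename(file), ": ",
         paste(unknown, collapse = ", "))
  }
  list(meta = meta, body = body)
}

#' Read a count screen
#'
#' Inverse of [write_counts()]. Counts are validated: a negative or
#' non-integer entry is an error naming the gene and sample.
#'
#' @param path directory written by [write_counts()].
#' @param dialect "rcc_like" or "tsv".
#' @return a `count_screen`.
#' @export
read_counts <- function(path, dialect = c("rcc_like", "tsv")) {
  dialect <- match.arg(dialect)
  panel <- read_panel(file.path(path, "panel.tsv"))
  if (dialect == "tsv") {
    tab <- read.delim(file.path(path, "counts.tsv"), check.names = FALSE,
                      stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab$symbol
    design <- read_design(file.path(path, "design.tsv"))
  } else {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no RCC-like sample files found in ", path)
    samples <- lapply(files, read_rcc_sample)
    metas <- lapply(samples, `[[`, "meta")
    design <- data.frame(
      sample_id = vapply(metas, `[[`, "", "Sample"),
      condition_id = as.integer(vapply(metas, `[[`, "", "Condition")),
      donor = as.integer(vapply(metas, `[[`, "", "Donor")),
      day = as.integer(vapply(metas, `[[`, "", "Day")),
      lane = as.integer(vapply(metas, `[[`, "", "Lane")),
      stringsAsFactors = FALSE
    )
    ord <- order(design$lane)
    design <- design[ord, ]
    samples <- samples[ord]
    rownames(design) <- NULL
    class(design) <- c("design_table", "data.frame")
    counts <- vapply(samples, function(s) {
      s$body$Count[match(panel$symbol, s$body$Name)]
    }, numeric(nrow(panel)))
    dimnames(counts) <- list(panel$symbol, design$sample_id)
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid count (negative or non-integer) for gene ",
         rownames(counts)[bad[1, 1]], " in sample ",
         colnames(counts)[bad[1, 2]])
  }
  storage.mode(counts) <- "integer"
  new_count_screen(counts, panel, design)
}
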