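#' Construct an analyte panel
#'
#' An `analyte_panel` is the pipeline's universal carrier: a samples x analytes
#' concentration matrix together with per-sample metadata (diagnostic class,
#' age, gender, APOE-like genotype, timepoint) and per-analyte metadata
#' (the least detectable dose, LDD). Concentrations are in analyte-specific
#' units on the raw scale, or dimensionless log10 units after
#' [log_transform()]; the `scale` field records which.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   analytes in columns (colnames = analyte ids). No negative entries.
#' @param sample_meta data.frame with one row per sample: columns `sample_id`,
#'   `class`, and optionally `age`, `gender`, `genotype` (e.g. `"e3/e4"`),
#'   `timepoint` (`"baseline"` or `"m12"`).
#' @param analyte_meta data.frame with one row per analyte: columns `analyte`
#'   and `ldd` (least detectable dose, same units as `values`; must be > 0).
#' @param scale `"raw"` or `"log10"`.
#' @return an object of class `analyte_panel`.
#' @export
analyte_panel <- function(values, sample_meta, analyte_meta, scale = "raw") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample rownames and analyte colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in values")
  if (!all(c("sample_id", "class") %in% names(sample_meta)))
    stop("sample_meta needs columns 'sample_id' and 'class'")
  if (!all(rownames(values) %in% sample_meta$sample_id))
    stop("every sample in values must appear in sample_meta")
  sample_meta <- sample_meta[match(rownames(values), sample_meta$sample_id), , drop = FALSE]
  if (anyNA(sample_meta$class)) stop("every sample must carry a class label")
  if (!all(c("analyte", "ldd") %in% names(analyte_meta)))
    stop("analyte_meta needs columns 'analyte' and 'ldd'")
  if (!all(colnames(values) %in% analyte_meta$analyte))
    stop("every analyte in values must appear in analyte_meta")
  analyte_meta <- analyte_meta[match(colnames(values), analyte_meta$analyte), , drop = FALSE]
  if (anyNA(analyte_meta$ldd) || any(analyte_meta$ldd <= 0))
    stop("LDD must be present and > 0 for every analyte: ",
         paste(analyte_meta$analyte[is.na(analyte_meta$ldd) | analyte_meta$ldd <= 0],
               collapse = ", "))
  scale <- match.arg(scale, c("raw", "log10"))
  if (scale == "raw" && any(values < 0))
    stop("raw concentrations cannot be negative")
  rownames(sample_meta) <- NULL
  rownames(analyte_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta,
                 analyte_meta = analyte_meta, scale = scale),
            class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat("analyte_panel:", nrow(x$values), "samples x", ncol(x$values),
      "analytes (", x$scale, "scale )\n")
  cat("classes:", paste(names(table(x$sample_meta$class)),
                        table(x$sample_meta$class), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.analyte_panel <- function(x) dim(x$values)

#' Subset a panel by samples and/or analytes
#'
#' @param panel an [analyte_panel()].
#' @param samples character vector of sample ids (or logical/integer index).
#' @param analytes character vector of analyte ids (or logical/integer index).
#' @return the subsetted `analyte_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, analytes = NULL) {
  stopifnot(inherits(panel, "analyte_panel"))
  v <- panel$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(analytes)) v <- v[, analytes, drop = FALSE]
  if (nrow(v) == 0L || ncol(v) == 0L) stop("subset leaves an empty panel")
  analyte_panel(v,
                panel$sample_meta[panel$sample_meta$sample_id %in% rownames(v), , drop = FALSE],
                panel$analyte_meta[panel$analyte_meta$analyte %in% colnames(v), , drop = FALSE],
                scale = panel$scale)
}

#' Class labels of a panel, in sample order
#' @param panel an [analyte_panel()].
#' @return character vector of class labels aligned with `rownames(panel$values)`.
#' @export
panel_classes <- function(panel) {
  stats::setNames(as.character(panel$sample_meta$class), panel$sample_meta$sample_id)
}

#' Write a panel to plain-text TSV files
#'
#' Writes `values.tsv` (samples x analytes, first column `sample_id`),
#' `sample_meta.tsv` and `analyte_meta.tsv` into `dir`.
#'
#' @param panel an [analyte_panel()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vals <- data.frame(sample_id = rownames(panel$values), panel$values,
                     check.names = FALSE)
  utils::write.table(vals, file.path(dir, "values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$sample_meta, file.path(dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$analyte_meta, file.path(dir, "analyte_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(panel$scale, file.path(dir, "scale.txt"))
  invisible(dir)
}

#' Read a panel written by [write_panel()]
#'
#' Missing values (empty fields) are rejected: the design assumes complete
#' post-QC matrices.
#'
#' @param dir directory containing `values.tsv`, `sample_meta.tsv`,
#'   `analyte_meta.tsv` (and optionally `scale.txt`).
#' @return an [analyte_panel()].
#' @export
read_panel <- function(dir) {
  vals <- utils::read.delim(file.path(dir, "values.tsv"), check.names = FALSE)
  if (anyNA(vals)) stop("missing values in values.tsv are not supported")
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- as.character(vals[[1]])
  sm <- utils::read.delim(file.path(dir, "sample_meta.tsv"))
  sm$sample_id <- as.character(sm$sample_id)
  am <- utils::read.delim(file.path(dir, "analyte_meta.tsv"))
  am$analyte <- as.character(am$analyte)
  scale_file <- file.path(dir, "scale.txt")
  sc <- if (file.exists(scale_file)) readLines(scale_file, n = 1) else "raw"
  analyte_panel(m, sm, am, scale = sc)
}
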