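#' Expression matrix with sample groups
#'
#' A light container for a features-by-samples expression matrix together
#' with the per-sample group label (benign vs tumour), the assay type, and
#' an optional per-feature biotype (lncRNA / mRNA / miRNA).
#'
#' @param values numeric matrix, rows = features, columns = samples. Row and
#'   column names are the feature and sample identifiers and must be unique.
#' @param groups character vector, one of `"benign"` / `"tumour"` per sample.
#' @param assay `"array"` (log2 intensities) or `"rnaseq"` (raw counts).
#' @param biotype optional character vector per feature, values in
#'   `c("lncRNA", "mRNA", "miRNA")`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `groups`, `assay`, `biotype`, plus `size_factors` after normalization.
#' @export
expr_matrix <- function(values, groups, assay = c("array", "rnaseq"),
                        biotype = NULL) {
  assay <- match.arg(assay)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (length(groups) != ncol(values))
    stop("`groups` must label every sample")
  groups <- as.character(groups)
  if (!all(groups %in% c("benign", "tumour")))
    stop("groups must be 'benign' or 'tumour'")
  if (assay == "rnaseq") {
    if (any(values < 0) || any(values != round(values)))
      stop("rnaseq counts must be non-negative integers")
  }
  if (!is.null(biotype)) {
    if (length(biotype) != nrow(values))
      stop("`biotype` must label every feature")
    if (!all(biotype %in% c("lncRNA", "mRNA", "miRNA")))
      stop("biotype values must be lncRNA, mRNA or miRNA")
  }
  structure(
    list(values = values, groups = groups, assay = assay, biotype = biotype,
         size_factors = NULL),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$assay))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$biotype)) {
    bt <- table(x$biotype)
    cat("  biotype:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature ids
#'
#' @param x an [expr_matrix()].
#' @param features character vector of feature ids to keep.
#' @return an `expr_matrix` restricted to `features`, order preserved.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(features, rownames(x$values))
  if (length(missing))
    stop("unknown feature ids: ", paste(utils::head(missing, 5), collapse = ", "))
  idx <- match(features, rownames(x$values))
  out <- x
  out$values <- x$values[idx, , drop = FALSE]
  if (!is.null(x$biotype)) out$biotype <- x$biotype[idx]
  out
}

#' Write / read an expression matrix as TSV plus a group sidecar
#'
#' The TSV has the feature id in the first column (`feature_id`) and one
#' column per sample; the sidecar is a two-column TSV (`sample_id`, `group`).
#'
#' @param x an [expr_matrix()].
#' @param path output TSV path for the matrix.
#' @param groups_path output TSV path for the group sidecar.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, groups_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(sample_id = colnames(x$values), group = x$groups,
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$biotype)) {
    bt_path <- paste0(sub("\\.tsv$", "", path), ".biotype.tsv")
    utils::write.table(
      data.frame(feature_id = rownames(x$values), biotype = x$biotype),
      bt_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname write_expression
#' @param assay assay type of the stored matrix.
#' @param biotype_path optional biotype sidecar (feature_id, biotype TSV).
#' @export
read_expression <- function(path, groups_path, assay = c("array", "rnaseq"),
                            biotype_path = NULL) {
  assay <- match.arg(assay)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  gdf <- utils::read.table(groups_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  groups <- gdf$group[match(colnames(values), gdf$sample_id)]
  if (anyNA(groups)) stop("group sidecar does not cover all samples")
  biotype <- NULL
  if (!is.null(biotype_path)) {
    bt <- utils::read.table(biotype_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    biotype <- bt$biotype[match(rownames(values), bt$feature_id)]
  }
  expr_matrix(values, groups, assay, biotype)
}
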