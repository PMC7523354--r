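#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param path GMT file.
#' @param namespace optional collection tag (e.g. `"GO-BP"`, `"KEGG"`).
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of member id vectors) and `namespace`.
#' @export
read_gmt <- function(path, namespace = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3
  if (any(bad)) stop("GMT line(s) without members: ", which(bad)[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  structure(list(sets = sets, namespace = namespace),
            class = "gene_set_collection")
}

#' Over-representation analysis (hypergeometric)
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between `gene_list` and the set, both restricted
#' to `background`. With `ease = TRUE` the overlap is decremented by one
#' before computing (the conservative DAVID-style variant). P-values are
#' BH-adjusted across the collection and results are sorted ascending by p
#' (ties by set name).
#'
#' @param gene_list character vector of genes of interest (subset of the
#'   background).
#' @param collection a [read_gmt()] result or a named list of id vectors.
#' @param background gene universe; defaults to the union of all collection
#'   members.
#' @param ease apply the overlap-minus-one correction.
#' @return data frame: `set_name`, `overlap_count`, `list_size`, `set_size`,
#'   `background_size`, `percent` (overlap / list size x 100), `p`, `p_adj`.
#' @export
ora <- function(gene_list, collection, background = NULL, ease = FALSE) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  if (!length(sets) || any(!vapply(sets, length, 0L)))
    stop("collection must contain non-empty sets")
  if (is.null(background)) background <- unique(unlist(sets))
  background <- unique(background)
  gene_list <- unique(gene_list)
  if (!length(gene_list) || !length(background))
    stop("gene list and background must be non-empty")
  if (!all(gene_list %in% background))
    stop("gene_list must be a subset of the background")
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], background)
    K <- length(members)
    k <- length(intersect(gene_list, members))
    k_eff <- if (ease) max(k - 1, 0) else k
    p <- stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, list_size = n, set_size = K,
               background_size = N, percent = 100 * k / n, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top enrichment rows, report-style
#'
#' First `k` rows of a sorted [ora()] result with the Count / % / P-Value
#' report columns. Ties in p keep the stable set-name order.
#'
#' @param results sorted [ora()] output.
#' @param k number of rows (default 15).
#' @return data frame `term`, `count`, `percent`, `p_value`, `p_adj`.
#' @export
top_table <- function(results, k = 15) {
  top <- utils::head(results, k)
  data.frame(term = top$set_name, count = top$overlap_count,
             percent = round(top$percent, 3), p_value = top$p,
             p_adj = top$p_adj, stringsAsFactors = FALSE)
}
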