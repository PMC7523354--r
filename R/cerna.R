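#' Pearson correlation with a t-distribution p-value
#'
#' Product-moment correlation of two vectors and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom;
#' `|r| = 1` gives `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero variance.
#' @param id_a,id_b optional feature ids carried into the result.
#' @return one-row data frame: `id_a`, `id_b`, `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y, id_a = "x", id_b = "y") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("n >= 3 required for a p-value")
  if (stats::sd(x) == 0) stop("zero variance in '", id_a, "'")
  if (stats::sd(y) == 0) stop("zero variance in '", id_b, "'")
  r <- stats::cor(x, y)
  p <- cor_pvalue(r, n)
  data.frame(id_a = id_a, id_b = id_b, r = r, p = p, n = n,
             stringsAsFactors = FALSE)
}

# two-sided p for a Pearson r at sample size n
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                            lower.tail = FALSE))
  p
}

#' Coexpressed lncRNA-mRNA pairs
#'
#' All (lncRNA, mRNA) pairs with Pearson `r > r_min` and two-sided
#' `p < p_max`, both strict. Matrices must already be on the correlation
#' scale (log2 of normalized counts for RNA-seq) and share sample columns.
#'
#' @param lnc_values,mrna_values numeric matrices, rows = features (ids in
#'   row names), columns = the same samples in the same order.
#' @param r_min correlation cutoff (default 0.4, exclusive).
#' @param p_max p-value cutoff (default 0.01, exclusive).
#' @return data frame `lncrna_id`, `mrna_id`, `r`, `p`, sorted by descending
#'   `r`.
#' @export
coexpression_pairs <- function(lnc_values, mrna_values, r_min = 0.4,
                               p_max = 0.01) {
  if (ncol(lnc_values) != ncol(mrna_values) ||
      !identical(colnames(lnc_values), colnames(mrna_values)))
    stop("lncRNA and mRNA matrices must share sample columns (same order)")
  n <- ncol(lnc_values)
  if (n < 3) stop("at least 3 shared samples required")
  rmat <- stats::cor(t(lnc_values), t(mrna_values))
  pmat <- cor_pvalue(rmat, n)
  hit <- which(rmat > r_min & pmat < p_max, arr.ind = TRUE)
  out <- data.frame(
    lncrna_id = rownames(rmat)[hit[, 1]],
    mrna_id = colnames(rmat)[hit[, 2]],
    r = rmat[hit], p = pmat[hit], stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble ceRNA triplets by miRNA anti-correlation
#'
#' A coexpressed (lncRNA, mRNA) pair and a miRNA form a triplet when the
#' miRNA targets both members (per the retained prediction records) and both
#' members oppose the miRNA:
#' \describe{
#'   \item{`de_direction`}{the miRNA's log2 fold change has the opposite
#'     sign to both the lncRNA's and the mRNA's. The default, usable when
#'     the miRNA cohorts and the RNA cohort have disjoint samples.}
#'   \item{`matched_samples`}{Pearson correlation of each member with the
#'     miRNA's expression on shared samples is negative (and `p < p_max_neg`
#'     when set). Requires `mirna_values` on the same samples as
#'     `rna_values`.}
#' }
#'
#' @param pairs [coexpression_pairs()] output.
#' @param records retained prediction records (after [vote_filter()] and
#'   [merge_with_de()]).
#' @param mode `"de_direction"` or `"matched_samples"`.
#' @param mirna_log2fc named numeric: miRNA log2 fold changes
#'   (de_direction mode).
#' @param gene_log2fc named numeric: lncRNA/mRNA log2 fold changes
#'   (de_direction mode).
#' @param mirna_values,rna_values matrices sharing sample columns
#'   (matched_samples mode).
#' @param p_max_neg optional p cutoff on the negative correlations
#'   (matched_samples mode); `NULL` applies no p threshold.
#' @return data frame of triplets: `lncrna_id`, `mirna_id`, `mrna_id`,
#'   `pair_r`, `pair_p`, `lnc_mirna_assoc`, `mrna_mirna_assoc` (signed
#'   association evidence: correlations or miRNA-vs-gene fold-change sign
#'   products, negative by construction).
#' @export
anticorrelation_filter <- function(pairs, records,
                                   mode = c("de_direction", "matched_samples"),
                                   mirna_log2fc = NULL, gene_log2fc = NULL,
                                   mirna_values = NULL, rna_values = NULL,
                                   p_max_neg = NULL) {
  mode <- match.arg(mode)
  empty <- data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character(), pair_r = numeric(),
                      pair_p = numeric(), lnc_mirna_assoc = numeric(),
                      mrna_mirna_assoc = numeric(), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0 || nrow(records) == 0) return(empty)
  if (mode == "de_direction") {
    if (is.null(mirna_log2fc) || is.null(gene_log2fc))
      stop("de_direction mode needs mirna_log2fc and gene_log2fc")
  } else {
    if (is.null(mirna_values) || is.null(rna_values))
      stop("matched_samples mode needs mirna_values and rna_values")
    shared <- intersect(colnames(mirna_values), colnames(rna_values))
    if (length(shared) < 3)
      stop("matched_samples mode requires >= 3 shared samples between the ",
           "miRNA and RNA matrices")
    mirna_values <- mirna_values[, shared, drop = FALSE]
    rna_values <- rna_values[, shared, drop = FALSE]
  }
  targets_of <- split(records$target_id, records$mirna_id)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lnc <- pairs$lncrna_id[i]; mrna <- pairs$mrna_id[i]
    common <- names(targets_of)[vapply(targets_of, function(t)
      lnc %in% t && mrna %in% t, TRUE)]
    if (!length(common)) next
    rows <- lapply(common, function(m) {
      if (mode == "de_direction") {
        fc_m <- mirna_log2fc[[m]]; fc_l <- gene_log2fc[[lnc]]
        fc_g <- gene_log2fc[[mrna]]
        if (is.null(fc_m) || is.null(fc_l) || is.null(fc_g) ||
            anyNA(c(fc_m, fc_l, fc_g))) return(NULL)
        a_l <- sign(fc_m) * sign(fc_l); a_g <- sign(fc_m) * sign(fc_g)
        if (a_l >= 0 || a_g >= 0) return(NULL)
        assoc <- c(a_l, a_g)
      } else {
        if (!m %in% rownames(mirna_values) ||
            !all(c(lnc, mrna) %in% rownames(rna_values))) return(NULL)
        n <- ncol(rna_values)
        r_l <- stats::cor(mirna_values[m, ], rna_values[lnc, ])
        r_g <- stats::cor(mirna_values[m, ], rna_values[mrna, ])
        if (is.na(r_l) || is.na(r_g) || r_l >= 0 || r_g >= 0) return(NULL)
        if (!is.null(p_max_neg) &&
            (cor_pvalue(r_l, n) >= p_max_neg || cor_pvalue(r_g, n) >= p_max_neg))
          return(NULL)
        assoc <- c(r_l, r_g)
      }
      data.frame(lncrna_id = lnc, mirna_id = m, mrna_id = mrna,
                 pair_r = pairs$r[i], pair_p = pairs$p[i],
                 lnc_mirna_assoc = assoc[1], mrna_mirna_assoc = assoc[2],
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Build the tripartite ceRNA network from triplets
#'
#' Nodes are the union of triplet members with their class; edges are the
#' deduplicated lncRNA-miRNA and miRNA-mRNA pairs of the triplets. The
#' triplet list is retained as provenance.
#'
#' @param triplets [anticorrelation_filter()] output (may be empty).
#' @return an object of class `cerna_network`: list with `nodes` (data frame
#'   `id`, `class`), `edges` (data frame `from`, `to`, `type`) and
#'   `triplets`.
#' @export
build_network <- function(triplets) {
  k <- nrow(triplets)
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna_id, class = rep("lncRNA", k),
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna_id, class = rep("miRNA", k),
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna_id, class = rep("mRNA", k),
               stringsAsFactors = FALSE)))
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup))
    stop("conflicting node class for id(s): ",
         paste(unique(dup), collapse = ", "))
  edges <- unique(rbind(
    data.frame(from = triplets$lncrna_id, to = triplets$mirna_id,
               type = rep("lnc-mir", k), stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               type = rep("mir-mrna", k), stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, triplets = triplets),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tab <- table(factor(x$nodes$class, c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("cerna_network: %d lncRNA, %d miRNA, %d mRNA nodes; %d edges (%d triplets)\n",
              tab["lncRNA"], tab["miRNA"], tab["mRNA"], nrow(x$edges),
              nrow(x$triplets)))
  invisible(x)
}

#' Hub scores for every lncRNA in the network
#'
#' For a lncRNA L: `n_lnc_mirna_pairs` is the number of distinct miRNAs in
#' triplets with L; `n_mirna_mrna_pairs` the number of distinct
#' (miRNA, mRNA) pairs over those triplets; `total` their sum. Ranked by
#' `total` descending, ties broken lexicographically by id. The top-ranked
#' lncRNAs are the hub candidates.
#'
#' @param network a [build_network()] result.
#' @return data frame `lncrna_id`, `n_lnc_mirna_pairs`, `n_mirna_mrna_pairs`,
#'   `total`.
#' @export
hub_scores <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  lncs <- network$nodes$id[network$nodes$class == "lncRNA"]
  tri <- network$triplets
  rows <- lapply(lncs, function(L) {
    sub <- tri[tri$lncrna_id == L, , drop = FALSE]
    data.frame(lncrna_id = L,
               n_lnc_mirna_pairs = length(unique(sub$mirna_id)),
               n_mirna_mrna_pairs = nrow(unique(sub[, c("mirna_id", "mrna_id")])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(lncrna_id = character(), n_lnc_mirna_pairs = integer(),
                      n_mirna_mrna_pairs = integer(), total = integer()))
  out$total <- out$n_lnc_mirna_pairs + out$n_mirna_mrna_pairs
  out <- out[order(-out$total, out$lncrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' First-neighbour subnetwork of one lncRNA
#'
#' The network induced by the triplets containing `lncrna_id` only: the hub,
#' its partner miRNAs, and the mRNAs paired through them. Its edge count
#' equals the hub's total pair score.
#'
#' @param network a [build_network()] result.
#' @param lncrna_id a lncRNA node id.
#' @return a `cerna_network`.
#' @export
extract_subnetwork <- function(network, lncrna_id) {
  stopifnot(inherits(network, "cerna_network"))
  if (!lncrna_id %in% network$nodes$id[network$nodes$class == "lncRNA"])
    stop("unknown lncRNA id: ", lncrna_id)
  build_network(network$triplets[network$triplets$lncrna_id == lncrna_id, ,
                                 drop = FALSE])
}

#' Network exporters
#'
#' `write_sif()` writes the Cytoscape SIF dialect
#' (`node<TAB>interaction<TAB>node`, interaction `lnc-mir` / `mir-mrna`);
#' `write_graphml()` writes GraphML with a `class` node attribute (via
#' igraph); `write_edgelist()` a plain `from`, `to`, `type` TSV.
#'
#' @param network a [build_network()] result.
#' @param path output file.
#' @return the network, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  writeLines(sprintf("%s\t%s\t%s", network$edges$from, network$edges$type,
                     network$edges$to), path)
  invisible(network)
}

#' @rdname write_sif
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(network)
}

#' @rdname write_sif
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(network)
}
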