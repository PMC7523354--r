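#' Median-of-ratios normalization for RNA-seq counts
#'
#' Computes per-sample size factors against a geometric-mean reference built
#' from the genes with no zero count in any sample; every gene is then
#' divided by its sample's size factor. This is the standard library-size
#' correction for count data.
#'
#' @param x an [expr_matrix()] with `assay = "rnaseq"`.
#' @return `x` with `values` replaced by normalized values (no longer integer
#'   counts; `assay` stays `"rnaseq"`) and `size_factors` set.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$assay != "rnaseq") stop("normalize_counts expects an rnaseq matrix")
  if (ncol(x$values) < 2) stop("at least 2 samples required")
  counts <- x$values
  if (all(counts == 0)) stop("degenerate input: all counts are zero")
  ref_rows <- rowSums(counts == 0) == 0
  if (!any(ref_rows))
    stop("degenerate input: every gene has a zero count; no reference genes")
  log_geo <- rowMeans(log(counts[ref_rows, , drop = FALSE]))
  sf <- apply(counts[ref_rows, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_geo)))
  out <- x
  out$values <- sweep(counts, 2, sf, "/")
  out$size_factors <- sf
  out
}

#' Per-feature two-group differential expression (Welch t)
#'
#' Arrays: Welch two-sample t-test on the stored log2 intensities, with
#' log2 fold change the tumour-minus-benign mean difference. RNA-seq: the
#' matrix is median-of-ratios normalized first (unless size factors are
#' already present) and the same test runs on `log2(normalized + 1)`.
#'
#' @param x an [expr_matrix()]; both groups need >= 2 samples.
#' @return data frame (one row per feature): `feature_id`, `log2fc`, `p`,
#'   with `p_adj` and `passes` left for [bh_adjust()] / [de_filter()].
#' @export
de_test <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  for (g in c("benign", "tumour"))
    if (sum(x$groups == g) < 2)
      stop("group '", g, "' has fewer than 2 samples")
  if (x$assay == "rnaseq") {
    if (is.null(x$size_factors)) x <- normalize_counts(x)
    vals <- log2(x$values + 1)
  } else {
    vals <- x$values
  }
  tum <- vals[, x$groups == "tumour", drop = FALSE]
  ben <- vals[, x$groups == "benign", drop = FALSE]
  n1 <- ncol(tum); n2 <- ncol(ben)
  m1 <- rowMeans(tum); m2 <- rowMeans(ben)
  v1 <- apply(tum, 1, stats::var); v2 <- apply(ben, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0 & m1 == m2] <- 1  # constant equal groups carry no evidence
  data.frame(feature_id = rownames(vals), log2fc = m1 - m2, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (same order), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold filter on differential-expression results
#'
#' Keeps features with `|log2fc| > fc_threshold` and `p_adj < alpha`, both
#' strict, and reports the direction of change.
#'
#' @param results data frame with `feature_id`, `log2fc`, `p_adj` (add via
#'   [bh_adjust()] if absent but `p` is present).
#' @param fc_threshold absolute log2 fold-change cutoff (default 1).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return data frame `feature_id`, `log2fc`, `p_adj`, `direction`
#'   (`"up"`/`"down"`, tumour vs benign) for the passing features.
#' @export
de_filter <- function(results, fc_threshold = 1, alpha = 0.05) {
  if (is.null(results$p_adj)) {
    if (is.null(results$p)) stop("results need a p or p_adj column")
    results$p_adj <- bh_adjust(results$p)
  }
  keep <- abs(results$log2fc) > fc_threshold & results$p_adj < alpha
  out <- results[keep, c("feature_id", "log2fc", "p_adj"), drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Cross-cohort miRNA consensus
#'
#' A miRNA is a candidate when it passes the differential-expression filter
#' in at least `min_cohorts` cohorts. By default the log2 fold-change sign
#' must agree across the cohorts where it passes; set
#' `require_consistent_direction = FALSE` to count by membership alone.
#'
#' @param per_cohort list, one element per cohort: either a character vector
#'   of passing ids, or a [de_filter()] data frame (needed for the direction
#'   check).
#' @param min_cohorts minimum number of cohorts (default 2).
#' @param require_consistent_direction enforce a shared direction sign.
#' @return character vector of consensus miRNA ids, sorted.
#' @export
consensus_mirnas <- function(per_cohort, min_cohorts = 2,
                             require_consistent_direction = TRUE) {
  if (min_cohorts > length(per_cohort))
    stop("min_cohorts (", min_cohorts, ") exceeds the number of cohorts (",
         length(per_cohort), ")")
  as_df <- lapply(per_cohort, function(el) {
    if (is.data.frame(el))
      data.frame(feature_id = el$feature_id,
                 dir = if (!is.null(el$direction)) el$direction
                       else if (!is.null(el$log2fc)) ifelse(el$log2fc > 0, "up", "down")
                       else NA_character_,
                 stringsAsFactors = FALSE)
    else
      data.frame(feature_id = as.character(el),
                 dir = rep(NA_character_, length(el)),
                 stringsAsFactors = FALSE)
  })
  all_rows <- do.call(rbind, as_df)
  counts <- table(all_rows$feature_id)
  ids <- as.character(names(counts)[counts >= min_cohorts])
  if (require_consistent_direction) {
    ok <- vapply(ids, function(id) {
      dirs <- all_rows$dir[all_rows$feature_id == id]
      if (anyNA(dirs)) return(TRUE)  # no direction info available
      length(unique(dirs)) == 1
    }, TRUE)
    ids <- ids[ok]
  }
  sort(ids)
}

#' Relative expression by the ddCt method
#'
#' Fold change `2^(-ddCt)` with
#' `ddCt = (ct_target_sample - ct_ref_sample) - (ct_target_calibrator - ct_ref_calibrator)`,
#' the standard qRT-PCR quantification against a reference gene (e.g. GAPDH)
#' and a calibrator sample.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator same in the calibrator.
#' @return fold change (vectorized).
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
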