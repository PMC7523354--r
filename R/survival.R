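#' Readers for SEG, exon-model and clinical tables
#'
#' `read_seg()` reads the SEG dialect (`sample`, `chromosome`, `start`,
#' `end`, `num_probes`, `seg_mean`; header tolerated, common alternative
#' header spellings such as `Seg.CN`/`seg.mean`/`chrom`/`loc.start` are
#' normalized). `read_exons()` reads a per-gene exon coordinate CSV
#' (`gene_id`, `exon`, `chromosome`, `start`, `end`). `read_clinical()`
#' reads the patient CSV (`patient_id`, `os_months`, `os_event`,
#' `dfs_months`, `dfs_event`, `age`, `sex`, `stage`).
#'
#' @param path input file.
#' @return a data frame.
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  nm[nm %in% c("id", "sample_id")] <- "sample"
  nm[nm %in% c("chrom", "chr")] <- "chromosome"
  nm[nm %in% c("loc.start")] <- "start"
  nm[nm %in% c("loc.end")] <- "end"
  nm[nm %in% c("seg.mean", "segment_mean", "seg.cn")] <- "seg_mean"
  nm[nm %in% c("num.mark", "num_mark")] <- "num_probes"
  names(df) <- nm
  need <- c("sample", "chromosome", "start", "end", "seg_mean")
  if (!all(need %in% names(df)))
    stop("SEG file must provide columns: ", paste(need, collapse = ", "))
  if (any(df$start > df$end)) stop("SEG records with start > end")
  df
}

#' @rdname read_seg
#' @export
read_exons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(df)))
    stop("exon table must provide columns: ", paste(need, collapse = ", "))
  if (any(df$start > df$end)) stop("exon records with start > end")
  df
}

#' @rdname read_seg
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "os_months", "os_event")
  if (!all(need %in% names(df)))
    stop("clinical table must provide columns: ", paste(need, collapse = ", "))
  if (any(df$os_months < 0, na.rm = TRUE)) stop("negative survival times")
  df
}

# "chr11" / "Chr 11" / "11" -> "11"
norm_chrom <- function(x) sub("^chr\\s*", "", tolower(trimws(as.character(x))))

#' Call per-patient CNV deficiency for one gene
#'
#' A patient is deficient when at least one segment with
#' `seg_mean <= threshold` (inclusive) overlaps at least one of the gene's
#' exons by at least one base. Coordinates are treated as 1-based fully
#' closed on both sides; set `half_open = TRUE` if the SEG input uses
#' 0-based half-open coordinates (they are converted before matching).
#' Chromosome names are normalized by stripping any "chr" prefix.
#'
#' @param segments SEG data frame (see [read_seg()]).
#' @param exons exon data frame for a single gene (or filtered with
#'   `gene_id`).
#' @param gene_id gene to call when `exons` covers several genes.
#' @param threshold segment-mean cutoff, default -0.3, inclusive.
#' @param half_open input SEG coordinates are 0-based half-open.
#' @return named logical vector over the patients present in `segments`.
#' @export
call_cnv_deficiency <- function(segments, exons, gene_id = NULL,
                                threshold = -0.3, half_open = FALSE) {
  if (!is.null(gene_id)) exons <- exons[exons$gene_id == gene_id, , drop = FALSE]
  if ("gene_id" %in% names(exons) && length(unique(exons$gene_id)) > 1)
    stop("exons cover several genes; pass gene_id")
  if (!nrow(exons)) stop("no exons for the requested gene")
  patients <- unique(segments$sample)
  seg <- segments
  if (half_open) seg$start <- seg$start + 1L
  seg$chromosome <- norm_chrom(seg$chromosome)
  ex_chr <- norm_chrom(exons$chromosome)
  if (!any(seg$chromosome %in% ex_chr))
    stop("no segment on chromosome(s) ", paste(unique(ex_chr), collapse = ","),
         " after chromosome-name normalization")
  low <- seg[seg$seg_mean <= threshold, , drop = FALSE]
  deficient <- rep(FALSE, length(patients))
  names(deficient) <- patients
  for (j in seq_len(nrow(exons))) {
    hit <- low$chromosome == ex_chr[j] &
      low$start <= exons$end[j] & low$end >= exons$start[j]
    deficient[unique(low$sample[hit])] <- TRUE
  }
  deficient
}

#' Per-patient deficiency flags for every gene in an exon table
#'
#' @inheritParams call_cnv_deficiency
#' @return data frame: `patient_id` plus one logical column per gene.
#' @export
cnv_deficiency_table <- function(segments, exons, threshold = -0.3,
                                 half_open = FALSE) {
  genes <- unique(exons$gene_id)
  patients <- unique(segments$sample)
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (g in genes)
    out[[g]] <- unname(call_cnv_deficiency(segments, exons, gene_id = g,
                                           threshold = threshold,
                                           half_open = half_open)[patients])
  out
}

#' Kaplan-Meier median survival
#'
#' The smallest time at which the Kaplan-Meier survival estimate drops to
#' 0.5 or below; undefined (NA, `defined = FALSE`) when the curve never
#' reaches 0.5.
#'
#' @param times non-negative survival times.
#' @param events 0/1 event indicators.
#' @return list with `median` (numeric, NA when undefined) and `defined`.
#' @export
km_median <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  # smallest event time with S(t) <= 0.5 (not survfit's midpoint convention);
  # small tolerance absorbs rounding in the cumulative KM product
  idx <- which(fit$surv <= 0.5 + 1e-9)
  med <- if (length(idx)) fit$time[min(idx)] else NA_real_
  list(median = med, defined = !is.na(med))
}

cox_fit <- function(data, formula) {
  fit <- tryCatch(
    survival::coxph(formula, data = data, ties = "efron"),
    error = function(e) stop("Cox model failed: ", conditionMessage(e)),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(formula, data = data, ties = "efron"))
      if (grepl("converge|infinite", conditionMessage(w)))
        stop("Cox model did not converge (possible separation): ",
             conditionMessage(w))
      f
    })
  fit
}

endpoint_cols <- function(endpoint) {
  endpoint <- match.arg(tolower(endpoint), c("os", "dfs"))
  list(time = paste0(endpoint, "_months"), event = paste0(endpoint, "_event"))
}

#' Univariate Cox proportional-hazards screen
#'
#' Single-covariate Cox fit (Efron ties) of one clinical column against the
#' chosen endpoint; reports the Wald hazard ratio, 95% CI and p-value.
#'
#' @param patients clinical data frame (see [read_clinical()]); extra
#'   covariate columns (e.g. gene deficiency flags) may be merged in first.
#' @param covariate name of the covariate column.
#' @param endpoint `"os"` or `"dfs"`.
#' @return one-row data frame: `covariate`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p`, `n_total`, `n_events`.
#' @export
cox_univariate <- function(patients, covariate, endpoint = "os") {
  ep <- endpoint_cols(endpoint)
  x <- patients[[covariate]]
  if (is.null(x)) stop("unknown covariate: ", covariate)
  if (length(unique(x[!is.na(x)])) < 2)
    stop("covariate '", covariate, "' is constant")
  if (is.character(x)) patients[[covariate]] <- factor(x)
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                   ep$time, ep$event, covariate))
  fit <- cox_fit(patients, fml)
  s <- summary(fit)
  data.frame(covariate = covariate,
             hazard_ratio = unname(s$conf.int[1, "exp(coef)"]),
             ci_low = unname(s$conf.int[1, "lower .95"]),
             ci_high = unname(s$conf.int[1, "upper .95"]),
             p = unname(s$coefficients[1, "Pr(>|z|)"]),
             n_total = s$n, n_events = s$nevent,
             stringsAsFactors = FALSE)
}

#' Screen clinical covariates by univariate Cox p-value
#'
#' @inheritParams cox_univariate
#' @param covariates candidate covariate columns.
#' @param alpha significance cutoff (default 0.05, strict).
#' @return data frame `covariate`, `p`, `selected`.
#' @export
screen_covariates <- function(patients, covariates = c("age", "sex", "stage"),
                              endpoint = "os", alpha = 0.05) {
  rows <- lapply(covariates, function(cv)
    cox_univariate(patients, cv, endpoint)[, c("covariate", "p")])
  out <- do.call(rbind, rows)
  out$selected <- out$p < alpha
  out
}

#' Multivariate Cox model of CNV deficiency plus screened covariates
#'
#' For each gene flag, fits a joint Cox PH model of the deficiency indicator
#' and the covariates that passed the univariate screen, and attaches the
#' per-group Kaplan-Meier medians and event counts. The hazard-ratio column
#' is the Wald estimate for the deficiency flag.
#'
#' @param patients clinical data frame.
#' @param gene_flags data frame from [cnv_deficiency_table()] (`patient_id`
#'   plus one logical column per gene).
#' @param screened_covariates character vector of covariates to adjust for
#'   (typically `screen_covariates(...)$covariate[selected]`).
#' @param endpoint `"os"` or `"dfs"`.
#' @return data frame, one row per gene: `gene`, `endpoint`, group sizes,
#'   event counts and KM medians for the deficient / intact groups,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p`.
#' @export
cox_multivariate <- function(patients, gene_flags,
                             screened_covariates = character(),
                             endpoint = "os") {
  ep <- endpoint_cols(endpoint)
  merged <- merge(patients, gene_flags, by = "patient_id", sort = FALSE)
  if (nrow(merged) == 0) stop("no patients shared between clinical and CNV tables")
  if ("sex" %in% screened_covariates && is.character(merged$sex))
    merged$sex <- factor(merged$sex)
  genes <- setdiff(names(gene_flags), "patient_id")
  rows <- lapply(genes, function(g) {
    flag <- merged[[g]]
    if (length(unique(flag)) < 2)
      stop("deficiency flag for ", g, " is constant")
    rhs <- paste(c(sprintf("`%s`", g), screened_covariates), collapse = " + ")
    fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                     ep$time, ep$event, rhs))
    fit <- cox_fit(merged, fml)
    s <- summary(fit)
    idx <- grep(g, rownames(s$conf.int), fixed = TRUE)[1]
    med_def <- km_median(merged[[ep$time]][flag], merged[[ep$event]][flag])
    med_int <- km_median(merged[[ep$time]][!flag], merged[[ep$event]][!flag])
    data.frame(gene = g, endpoint = toupper(endpoint),
               n_deficient = sum(flag),
               events_deficient = sum(merged[[ep$event]][flag]),
               median_deficient = med_def$median,
               n_intact = sum(!flag),
               events_intact = sum(merged[[ep$event]][!flag]),
               median_intact = med_int$median,
               hazard_ratio = unname(s$conf.int[idx, "exp(coef)"]),
               ci_low = unname(s$conf.int[idx, "lower .95"]),
               ci_high = unname(s$conf.int[idx, "upper .95"]),
               p = unname(s$coefficients[idx, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
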