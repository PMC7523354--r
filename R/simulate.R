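#' Simulation configuration for the synthetic ceRNA study
#'
#' Bundles every knob of the synthetic-data generators: cohort sizes, feature
#' counts, the planted effect sizes, the negative-binomial noise level, the
#' target-programme vote ranges, and the CNV/survival parameters. Defaults
#' emulate the study design the pipeline is built for: three small array
#' miRNA cohorts (8/23, 11/20 and 9/92 benign/tumour samples), one RNA-seq
#' cohort of 30 benign + 30 tumour samples, and a 537-patient CNV/survival
#' cohort.
#'
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @param mirna_cohorts list of `c(n_benign, n_tumour)` per array cohort.
#' @param n_benign_rna,n_tumor_rna RNA-seq cohort group sizes.
#' @param n_mirnas,n_lncrnas,n_mrnas feature counts.
#' @param n_planted_triplets number of planted (lncRNA, miRNA, mRNA) triplets.
#' @param n_decoy_mirnas miRNAs differentially expressed in exactly one
#'   cohort (must not survive the >=2-cohort consensus).
#' @param de_log2fc magnitude (log2 units) of the planted miRNA shift;
#'   planted miRNAs go down in tumour, their lncRNA/mRNA partners up.
#' @param rna_de_log2fc log2 shift of planted lncRNAs/mRNAs in tumour.
#' @param sponge_rho target Pearson correlation of planted lncRNA-mRNA pairs,
#'   in (0, 1).
#' @param anti_rho target correlation of each planted gene with its miRNA's
#'   latent activity, in (-1, 0).
#' @param nb_dispersion negative-binomial dispersion of the RNA-seq counts.
#' @param program_names labels of the 7 target-prediction programmes.
#' @param true_vote_range,decoy_vote_range integer vote ranges (within 0..7)
#'   for planted and decoy prediction rows.
#' @param n_decoy_predictions decoy rows in the target table.
#' @param n_patients CNV/survival cohort size.
#' @param cnv_del_fraction fraction of patients carrying a deletion over each
#'   gene's exons.
#' @param baseline_hazard monthly baseline event hazard.
#' @param log_hr_deficient log hazard ratio of CNV deficiency (first gene).
#' @param log_hr_stage log hazard ratio per AJCC stage step (stage is the one
#'   prognostic clinical covariate; age and sex are null).
#' @param censoring_rate target fraction of censored survival times.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       mirna_cohorts = list(c(8, 23), c(11, 20), c(9, 92)),
                       n_benign_rna = 30, n_tumor_rna = 30,
                       n_mirnas = 20, n_lncrnas = 50, n_mrnas = 200,
                       n_planted_triplets = 10,
                       n_decoy_mirnas = 3,
                       de_log2fc = 3,
                       rna_de_log2fc = 2,
                       sponge_rho = 0.9, anti_rho = -0.8,
                       nb_dispersion = 0.05,
                       program_names = c("PITA", "RNA22", "miRmap",
                                         "DIANA-microT", "miRanda", "PicTar",
                                         "TargetScan"),
                       true_vote_range = c(4, 7),
                       decoy_vote_range = c(1, 3),
                       n_decoy_predictions = 100,
                       n_patients = 537,
                       cnv_del_fraction = 0.15,
                       baseline_hazard = 0.02,
                       log_hr_deficient = log(2),
                       log_hr_stage = 0.3,
                       censoring_rate = 0.3) {
  cfg <- list(seed = as.integer(seed), mirna_cohorts = mirna_cohorts,
              n_benign_rna = n_benign_rna, n_tumor_rna = n_tumor_rna,
              n_mirnas = n_mirnas, n_lncrnas = n_lncrnas, n_mrnas = n_mrnas,
              n_planted_triplets = n_planted_triplets,
              n_decoy_mirnas = n_decoy_mirnas,
              de_log2fc = de_log2fc, rna_de_log2fc = rna_de_log2fc,
              sponge_rho = sponge_rho, anti_rho = anti_rho,
              nb_dispersion = nb_dispersion, program_names = program_names,
              true_vote_range = true_vote_range,
              decoy_vote_range = decoy_vote_range,
              n_decoy_predictions = n_decoy_predictions,
              n_patients = n_patients, cnv_del_fraction = cnv_del_fraction,
              baseline_hazard = baseline_hazard,
              log_hr_deficient = log_hr_deficient,
              log_hr_stage = log_hr_stage,
              censoring_rate = censoring_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  counts <- c(cfg$n_benign_rna, cfg$n_tumor_rna, cfg$n_mirnas, cfg$n_lncrnas,
              cfg$n_mrnas, cfg$n_patients, unlist(cfg$mirna_cohorts))
  chk(all(counts >= 1), "all sample/feature counts must be >= 1")
  chk(cfg$n_planted_triplets >= 0, "n_planted_triplets must be >= 0")
  chk(cfg$sponge_rho > 0 && cfg$sponge_rho < 1, "sponge_rho must be in (0,1)")
  chk(cfg$anti_rho > -1 && cfg$anti_rho < 0, "anti_rho must be in (-1,0)")
  chk(cfg$anti_rho^2 + abs(cfg$sponge_rho - cfg$anti_rho^2) <= 1,
      "anti_rho^2 + |sponge_rho - anti_rho^2| must not exceed 1")
  chk(cfg$nb_dispersion > 0, "nb_dispersion must be > 0")
  chk(length(cfg$program_names) == 7, "exactly 7 programme names expected")
  for (rng in list(cfg$true_vote_range, cfg$decoy_vote_range))
    chk(length(rng) == 2 && rng[1] <= rng[2] && rng[1] >= 0 && rng[2] <= 7,
        "vote ranges must be within [0, 7]")
  chk(cfg$cnv_del_fraction >= 0 && cfg$cnv_del_fraction <= 1,
      "cnv_del_fraction must be in [0,1]")
  chk(cfg$baseline_hazard > 0, "baseline_hazard must be > 0")
  chk(cfg$censoring_rate >= 0 && cfg$censoring_rate < 1,
      "censoring_rate must be in [0,1)")
  chk(cfg$n_planted_triplets <= min(cfg$n_mirnas, cfg$n_lncrnas, cfg$n_mrnas),
      "n_planted_triplets exceeds available features")
  invisible(cfg)
}

#' Read a simulation config from a YAML (or JSON) key-value file
#'
#' Unknown keys are rejected; missing keys take the [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown sim_config keys: ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

# Deterministic feature ids and planted-triplet assignment shared by all
# generators, so the array cohorts, the RNA-seq cohort and the target table
# agree on which ids are planted under one config.
planted_truth <- function(cfg) {
  mirna_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))
  lnc_ids <- sprintf("lnc-%03d", seq_len(cfg$n_lncrnas))
  mrna_ids <- sprintf("gene-%04d", seq_len(cfg$n_mrnas))
  set.seed(cfg$seed)
  k <- cfg$n_planted_triplets
  triplets <- data.frame(
    lncrna_id = if (k) sample(lnc_ids, k) else character(),
    mirna_id = if (k) sample(mirna_ids, k) else character(),
    mrna_id = if (k) sample(mrna_ids, k) else character(),
    stringsAsFactors = FALSE)
  free_mirnas <- setdiff(mirna_ids, triplets$mirna_id)
  n_decoy <- min(cfg$n_decoy_mirnas, length(free_mirnas))
  decoy_mirnas <- if (n_decoy) sample(free_mirnas, n_decoy) else character()
  list(mirna_ids = mirna_ids, lnc_ids = lnc_ids, mrna_ids = mrna_ids,
       triplets = triplets, planted_mirnas = unique(triplets$mirna_id),
       decoy_mirnas = decoy_mirnas)
}

#' Simulate array-based miRNA cohorts with a planted consensus signal
#'
#' Generates one log2-intensity matrix per cohort. Planted miRNAs (those of
#' the planted triplets) are shifted down in tumour samples by `de_log2fc`
#' in at least two cohorts; decoy miRNAs are shifted in exactly one cohort;
#' everything else is null Gaussian noise around a per-miRNA baseline.
#'
#' @param config a [sim_config()].
#' @return list with `cohorts` (list of [expr_matrix()], assay `"array"`) and
#'   `truth` (planted/decoy miRNA ids, per-cohort shifted sets, triplets).
#' @export
simulate_mirna_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- planted_truth(config)
  k <- length(config$mirna_cohorts)
  set.seed(config$seed + 101L)
  # planted miRNAs are shifted in a random subset of >= 2 cohorts
  planted_in <- lapply(tr$planted_mirnas, function(m) {
    if (k < 2) stop("at least two miRNA cohorts are required")
    sort(sample(k, sample(2:k, 1)))
  })
  names(planted_in) <- tr$planted_mirnas
  decoy_in <- stats::setNames(sample(k, length(tr$decoy_mirnas), replace = TRUE),
                              tr$decoy_mirnas)
  baseline <- stats::rnorm(config$n_mirnas, mean = 7, sd = 1.5)
  cohorts <- vector("list", k)
  shifted_by_cohort <- vector("list", k)
  for (i in seq_len(k)) {
    nb <- config$mirna_cohorts[[i]][1]
    nt <- config$mirna_cohorts[[i]][2]
    n <- nb + nt
    vals <- matrix(stats::rnorm(config$n_mirnas * n, sd = 1), config$n_mirnas, n) +
      baseline
    groups <- c(rep("benign", nb), rep("tumour", nt))
    shifted <- c(tr$planted_mirnas[vapply(planted_in, function(s) i %in% s, TRUE)],
                 names(decoy_in)[decoy_in == i])
    rownames(vals) <- tr$mirna_ids
    colnames(vals) <- sprintf("c%d_s%02d", i, seq_len(n))
    idx <- match(shifted, tr$mirna_ids)
    vals[idx, groups == "tumour"] <- vals[idx, groups == "tumour"] - config$de_log2fc
    shifted_by_cohort[[i]] <- shifted
    cohorts[[i]] <- expr_matrix(vals, groups, assay = "array",
                                biotype = rep("miRNA", config$n_mirnas))
  }
  list(cohorts = cohorts,
       truth = list(planted_mirnas = tr$planted_mirnas,
                    decoy_mirnas = tr$decoy_mirnas,
                    de_mirnas_by_cohort = shifted_by_cohort,
                    triplets = tr$triplets))
}

# mean-parameterized NB draw; size = 1/dispersion
rnb <- function(mu, dispersion) {
  stats::rnbinom(length(mu), mu = pmax(mu, 1e-8), size = 1 / dispersion)
}

#' Simulate an RNA-seq cohort with planted ceRNA triplets
#'
#' Counts are negative binomial with log-normal gene baselines. For each
#' planted triplet a latent per-sample miRNA activity drives the lncRNA and
#' mRNA log2 means so that the pair correlates about `sponge_rho` and each
#' member correlates about `anti_rho` with the activity; planted genes are
#' additionally shifted up in tumour by `rna_de_log2fc`. A matched miRNA
#' expression matrix (latent activity plus independent noise, on the same
#' samples) is emitted for matched-sample anti-correlation analysis.
#' Non-planted genes are null.
#'
#' @param config a [sim_config()].
#' @return list with `rna` (counts [expr_matrix()] with biotypes), `mirna`
#'   (matched array-scale [expr_matrix()]) and `truth`.
#' @export
simulate_rnaseq_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- planted_truth(config)
  nb <- config$n_benign_rna
  nt <- config$n_tumor_rna
  n <- nb + nt
  groups <- c(rep("benign", nb), rep("tumour", nt))
  samples <- sprintf("rna_s%03d", seq_len(n))
  gene_ids <- c(tr$lnc_ids, tr$mrna_ids)
  biotype <- c(rep("lncRNA", config$n_lncrnas), rep("mRNA", config$n_mrnas))
  set.seed(config$seed + 202L)
  base_log2 <- stats::rnorm(length(gene_ids), mean = 9, sd = 1)
  log2mu <- matrix(rep(base_log2, n), nrow = length(gene_ids), ncol = n)
  dimnames(log2mu) <- list(gene_ids, samples)

  effect_sd <- 1.5   # sd of the latent triplet signal on the log2 scale
  anti <- config$anti_rho
  delta <- config$sponge_rho - anti^2
  lambda <- sqrt(abs(delta))
  resid <- 1 - anti^2 - lambda^2
  ntrip <- nrow(tr$triplets)
  activity <- matrix(0, nrow = max(ntrip, 1), ncol = n)
  for (i in seq_len(ntrip)) {
    a <- stats::rnorm(n)               # latent miRNA activity
    s <- stats::rnorm(n)               # shared sponge factor
    sig_l <- anti * a + lambda * s + sqrt(resid) * stats::rnorm(n)
    sig_m <- anti * a + sign(delta) * lambda * s + sqrt(resid) * stats::rnorm(n)
    shift <- config$rna_de_log2fc * (groups == "tumour")
    log2mu[tr$triplets$lncrna_id[i], ] <-
      log2mu[tr$triplets$lncrna_id[i], ] + effect_sd * sig_l + shift
    log2mu[tr$triplets$mrna_id[i], ] <-
      log2mu[tr$triplets$mrna_id[i], ] + effect_sd * sig_m + shift
    activity[i, ] <- a
  }
  counts <- matrix(rnb(2^log2mu, config$nb_dispersion),
                   nrow = length(gene_ids), ncol = n, dimnames = dimnames(log2mu))
  rna <- expr_matrix(counts, groups, assay = "rnaseq", biotype = biotype)

  # matched miRNA observations: activity + independent measurement noise
  mir_vals <- matrix(stats::rnorm(config$n_mirnas * n, mean = 7, sd = 0.3),
                     config$n_mirnas, n,
                     dimnames = list(tr$mirna_ids, samples))
  for (i in seq_len(ntrip))
    mir_vals[tr$triplets$mirna_id[i], ] <-
      mir_vals[tr$triplets$mirna_id[i], ] + activity[i, ]
  mirna <- expr_matrix(mir_vals, groups, assay = "array",
                       biotype = rep("miRNA", config$n_mirnas))

  de_dir <- c(stats::setNames(rep(1, ntrip), tr$triplets$lncrna_id),
              stats::setNames(rep(1, ntrip), tr$triplets$mrna_id))
  list(rna = rna, mirna = mirna,
       truth = list(triplets = tr$triplets,
                    planted_lncrnas = tr$triplets$lncrna_id,
                    planted_mrnas = tr$triplets$mrna_id,
                    planted_mirnas = tr$planted_mirnas,
                    de_direction = de_dir))
}

#' Simulate a miRNA target-prediction table with programme votes
#'
#' Planted miRNA-to-lncRNA and miRNA-to-mRNA rows receive a number of
#' programme votes drawn from `true_vote_range`; decoy rows from
#' `decoy_vote_range`. Votes are realized as a comma-joined subset of the
#' seven programme labels.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_rnaseq_cohort()] (or any
#'   list with a `triplets` data frame); pass `NULL` or an empty triplet set
#'   for a decoy-only table.
#' @return data frame with columns `mirna_id`, `target_id`, `target_class`,
#'   `programs` (comma-joined labels).
#' @export
simulate_target_table <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tr <- planted_truth(config)
  triplets <- if (is.null(truth)) data.frame() else truth$triplets
  set.seed(config$seed + 303L)
  draw_programs <- function(n_rows, range) {
    vals <- seq(range[1], range[2])
    votes <- vals[sample.int(length(vals), n_rows, replace = TRUE)]
    vapply(votes, function(v)
      paste(sort(sample(config$program_names, v)), collapse = ","), "")
  }
  rows <- list()
  if (!is.null(triplets) && nrow(triplets)) {
    rows$true <- data.frame(
      mirna_id = rep(triplets$mirna_id, 2),
      target_id = c(triplets$lncrna_id, triplets$mrna_id),
      target_class = rep(c("lncRNA", "mRNA"), each = nrow(triplets)),
      programs = draw_programs(2 * nrow(triplets), config$true_vote_range),
      stringsAsFactors = FALSE)
  }
  nd <- config$n_decoy_predictions
  if (nd > 0) {
    all_targets <- c(tr$lnc_ids, tr$mrna_ids)
    classes <- c(rep("lncRNA", length(tr$lnc_ids)), rep("mRNA", length(tr$mrna_ids)))
    idx <- sample(length(all_targets), nd, replace = TRUE)
    decoys <- data.frame(
      mirna_id = sample(tr$mirna_ids, nd, replace = TRUE),
      target_id = all_targets[idx],
      target_class = classes[idx],
      programs = draw_programs(nd, config$decoy_vote_range),
      stringsAsFactors = FALSE)
    if (!is.null(rows$true)) {
      key <- paste(decoys$mirna_id, decoys$target_id)
      truekey <- paste(rows$true$mirna_id, rows$true$target_id)
      decoys <- decoys[!key %in% truekey, , drop = FALSE]
    }
    rows$decoy <- decoys
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), programs = character())
  rownames(out) <- NULL
  out[!duplicated(paste(out$mirna_id, out$target_id)), , drop = FALSE]
}

#' Simulate SEG copy-number calls and survival outcomes
#'
#' For each gene in `exons`, a fraction `cnv_del_fraction` of patients carry
#' a segment with segment mean drawn at or below -0.35 overlapping one of the
#' gene's exons; the remaining patients carry a copy-neutral segment over the
#' same region. Survival is exponential with hazard
#' `baseline_hazard * exp(log_hr_deficient * deficient_gene1 + log_hr_stage * (stage - 1))`,
#' with independent exponential censoring tuned to `censoring_rate`.
#' Disease-free survival uses 1.5x the baseline hazard, same linear predictor.
#'
#' @param config a [sim_config()].
#' @param exons exon model data frame (`gene_id`, `exon`, `chromosome`,
#'   `start`, `end`), e.g. [hub_lncrna_exons()].
#' @return list with `segments` (SEG-dialect data frame), `clinical`
#'   (patient data frame) and `truth$deficient_patients` (per-gene id sets).
#' @export
simulate_cnv_and_survival <- function(config, exons = hub_lncrna_exons()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  n <- config$n_patients
  patients <- sprintf("P%04d", seq_len(n))
  genes <- unique(exons$gene_id)
  seg_rows <- list()
  deficient <- list()
  for (g in genes) {
    ex <- exons[exons$gene_id == g, , drop = FALSE]
    n_def <- round(config$cnv_del_fraction * n)
    def_idx <- if (n_def) sample(n, n_def) else integer()
    deficient[[g]] <- patients[def_idx]
    pick <- sample(nrow(ex), n, replace = TRUE)
    is_def <- seq_len(n) %in% def_idx
    seg_mean <- ifelse(is_def, stats::runif(n, -1.2, -0.35),
                       stats::runif(n, -0.2, 0.2))
    # deficient segments sit inside one exon; neutral ones span the locus
    start <- ifelse(is_def, ex$start[pick], min(ex$start) - 5000L)
    end <- ifelse(is_def, ex$end[pick], max(ex$end) + 5000L)
    seg_rows[[g]] <- data.frame(
      sample = patients, chromosome = ex$chromosome[1],
      start = as.integer(start), end = as.integer(end),
      num_probes = sample(5:50, n, replace = TRUE),
      seg_mean = round(seg_mean, 4), stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL

  age <- round(stats::rnorm(n, 60, 12))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
  def1 <- patients %in% deficient[[genes[1]]]
  lp <- config$log_hr_deficient * def1 + config$log_hr_stage * (stage - 1)
  draw_endpoint <- function(base_h) {
    h <- base_h * exp(lp)
    t_event <- stats::rexp(n, rate = h)
    if (config$censoring_rate > 0) {
      hc <- mean(h) * config$censoring_rate / (1 - config$censoring_rate)
      t_cens <- stats::rexp(n, rate = hc)
    } else t_cens <- rep(Inf, n)
    list(time = round(pmin(t_event, t_cens), 2),
         event = as.integer(t_event <= t_cens))
  }
  os <- draw_endpoint(config$baseline_hazard)
  dfs <- draw_endpoint(config$baseline_hazard * 1.5)
  clinical <- data.frame(
    patient_id = patients,
    os_months = os$time, os_event = os$event,
    dfs_months = dfs$time, dfs_event = dfs$event,
    age = age, sex = sex, stage = stage, stringsAsFactors = FALSE)
  list(segments = segments, clinical = clinical,
       truth = list(deficient_patients = deficient))
}

#' hg19 exon models of the three hub lncRNAs
#'
#' Exon coordinates (1-based, fully closed, hg19) of MALAT1, LINC00943 and
#' LINC00261, the default gene models for CNV-deficiency calling.
#'
#' @return data frame with columns `gene_id`, `exon`, `chromosome`, `start`,
#'   `end`.
#' @export
hub_lncrna_exons <- function() {
  data.frame(
    gene_id = rep(c("MALAT1", "LINC00943", "LINC00261"), each = 4),
    exon = rep(1:4, 3),
    chromosome = rep(c("11", "12", "20"), each = 4),
    start = c(65265481L, 65265159L, 65266440L, 65273731L,
              127221553L, 127227286L, 127229316L, 127229552L,
              22559148L, 22548432L, 22547321L, 22541192L),
    end = c(65265876L, 65265336L, 65271376L, 65273902L,
            127221702L, 127228026L, 127229434L, 127230800L,
            22559280L, 22548523L, 22547443L, 22545754L),
    stringsAsFactors = FALSE)
}

#' Table writers for the synthetic artifacts
#'
#' Plain-text writers matching the readers of the analysis modules:
#' prediction TSV, SEG TSV, clinical CSV and GMT.
#'
#' @param x the table (or, for [write_gmt()], a named list of id vectors).
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_predictions <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_predictions
#' @export
write_seg <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_predictions
#' @export
write_clinical <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname write_predictions
#' @param descriptions optional per-set description column for the GMT.
#' @export
write_gmt <- function(x, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(x))
  lines <- vapply(seq_along(x), function(i)
    paste(c(names(x)[i], descriptions[i], x[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(x)
}
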