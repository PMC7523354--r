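#' Validate and normalize a pipeline configuration
#'
#' Fills defaults for every threshold of the workflow, range-checks them,
#' and rejects unknown keys. The config may come from [yaml::read_yaml()]
#' or be built in code.
#'
#' @param config named list. Recognized keys: `seed` (integer), `fc` (log2FC
#'   cutoff, > 0), `alpha` (adjusted-p cutoff in (0,1)), `min_cohorts`
#'   (>= 1), `min_programs` (1..7), `r_min` (in [0,1)), `p_max` (in (0,1)),
#'   `p_max_neg` (optional, in (0,1) or NULL), `cnv_threshold` (< 0),
#'   `screen_alpha` (in (0,1)), `anticorrelation_mode` (`"de_direction"` /
#'   `"matched_samples"`), `ease` (logical), `require_consistent_direction`
#'   (logical), `output_dir` (optional path), `sim` (list of [sim_config()]
#'   overrides for synthetic runs).
#' @return the normalized config (class `pipeline_config`) with defaults
#'   echoed.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(seed = 1L, fc = 1, alpha = 0.05, min_cohorts = 2L,
                   min_programs = 4L, r_min = 0.4, p_max = 0.01,
                   p_max_neg = NULL, cnv_threshold = -0.3,
                   screen_alpha = 0.05,
                   anticorrelation_mode = "de_direction", ease = FALSE,
                   require_consistent_direction = TRUE,
                   output_dir = NULL, sim = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  bad <- function(key, allowed)
    stop("config key '", key, "' = ", deparse(cfg[[key]]),
         " outside allowed range ", allowed, call. = FALSE)
  if (!is.numeric(cfg$fc) || cfg$fc < 0) bad("fc", ">= 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) bad("alpha", "(0, 1)")
  if (cfg$min_cohorts < 1) bad("min_cohorts", ">= 1")
  if (cfg$min_programs < 1 || cfg$min_programs > 7) bad("min_programs", "1..7")
  if (cfg$r_min < 0 || cfg$r_min >= 1) bad("r_min", "[0, 1)")
  if (cfg$p_max <= 0 || cfg$p_max >= 1) bad("p_max", "(0, 1)")
  if (!is.null(cfg$p_max_neg) && (cfg$p_max_neg <= 0 || cfg$p_max_neg >= 1))
    bad("p_max_neg", "(0, 1) or NULL")
  if (cfg$cnv_threshold >= 0) bad("cnv_threshold", "< 0")
  if (cfg$screen_alpha <= 0 || cfg$screen_alpha >= 1) bad("screen_alpha", "(0, 1)")
  if (!cfg$anticorrelation_mode %in% c("de_direction", "matched_samples"))
    bad("anticorrelation_mode", "de_direction | matched_samples")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full ceRNA inference workflow on synthetic data
#'
#' Executes the stages in order — simulate inputs, per-cohort miRNA
#' differential expression, cross-cohort consensus, RNA-seq differential
#' expression, target vote filtering and DE merge, miRNA pruning,
#' coexpression pairs, anti-correlation triplets, network assembly, hub
#' scoring, optional enrichment, and the CNV-deficiency Cox survival screen —
#' and returns a manifest of every count and parameter plus the stage
#' results. Deterministic given `seed`. When `output_dir` is set, each
#' stage's artifact is persisted as TSV/CSV before the next stage runs.
#'
#' @param config a [validate_config()] result (or a plain list passed
#'   through it).
#' @param collection optional gene-set collection for the enrichment stage.
#' @param verbose log stage progress.
#' @return list with `manifest` (parameters and counts per stage) and
#'   `results` (the stage objects: DE tables, consensus, records, pairs,
#'   triplets, network, hub table, enrichment, survival, plus the simulation
#'   ground truth).
#' @export
run_pipeline <- function(config = list(), collection = NULL, verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  persist <- function(obj, name) {
    if (!is.null(out_dir))
      utils::write.table(obj, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    obj
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------
  stage_log(verbose, "simulate: seed %d", config$seed)
  scfg <- run_stage("simulate",
                    do.call(sim_config, c(list(seed = config$seed), config$sim)))
  mir <- run_stage("simulate", simulate_mirna_cohorts(scfg))
  rna <- run_stage("simulate", simulate_rnaseq_cohort(scfg))
  preds <- run_stage("simulate", simulate_target_table(scfg, rna$truth))
  cnv <- run_stage("simulate", simulate_cnv_and_survival(scfg))

  # -- miRNA DE + consensus ---------------------------------------------
  de_mir <- run_stage("diffexpr_mirna", lapply(mir$cohorts, function(co) {
    res <- de_test(co)
    res$p_adj <- bh_adjust(res$p)
    res
  }))
  passing <- lapply(de_mir, de_filter, fc_threshold = config$fc,
                    alpha = config$alpha)
  demis <- run_stage("consensus", consensus_mirnas(
    passing, min_cohorts = config$min_cohorts,
    require_consistent_direction = config$require_consistent_direction))
  stage_log(verbose, "consensus: %d candidate miRNAs", length(demis))

  # -- RNA DE ------------------------------------------------------------
  rna_norm <- run_stage("diffexpr_rna", normalize_counts(rna$rna))
  de_rna <- run_stage("diffexpr_rna", {
    res <- de_test(rna_norm)
    res$p_adj <- bh_adjust(res$p)
    res
  })
  de_pass <- de_filter(de_rna, fc_threshold = config$fc, alpha = config$alpha)
  biotype <- stats::setNames(rna$rna$biotype, rownames(rna$rna$values))
  de_lncrnas <- de_pass$feature_id[biotype[de_pass$feature_id] == "lncRNA"]
  de_mrnas <- de_pass$feature_id[biotype[de_pass$feature_id] == "mRNA"]
  persist(de_pass, "de_rna_passing")

  # -- targets -----------------------------------------------------------
  voted <- run_stage("targets", vote_filter(preds, config$min_programs))
  voted <- voted[voted$mirna_id %in% demis, , drop = FALSE]
  merged <- run_stage("targets", suppressWarnings(
    merge_with_de(voted, de_mrnas, de_lncrnas)))
  pruned <- prune_mirnas(merged$records, demis)
  persist(merged$records, "retained_predictions")
  stage_log(verbose, "targets: %d records, %d miRNAs kept",
            nrow(merged$records), length(pruned$kept))

  # -- ceRNA network -----------------------------------------------------
  log_norm <- log2(rna_norm$values + 1)
  pairs <- run_stage("coexpression", {
    if (length(merged$dels) && length(merged$dems))
      coexpression_pairs(log_norm[merged$dels, , drop = FALSE],
                         log_norm[merged$dems, , drop = FALSE],
                         r_min = config$r_min, p_max = config$p_max)
    else
      data.frame(lncrna_id = character(), mrna_id = character(),
                 r = numeric(), p = numeric())
  })
  mir_fc <- rowMeans(do.call(cbind, lapply(de_mir, function(d)
    stats::setNames(d$log2fc, d$feature_id)[demis])), na.rm = TRUE)
  names(mir_fc) <- demis
  gene_fc <- stats::setNames(de_rna$log2fc, de_rna$feature_id)
  triplets <- run_stage("triplets", {
    recs <- merged$records[merged$records$mirna_id %in% pruned$kept, , drop = FALSE]
    if (config$anticorrelation_mode == "de_direction")
      anticorrelation_filter(pairs, recs, mode = "de_direction",
                             mirna_log2fc = mir_fc, gene_log2fc = gene_fc,
                             p_max_neg = config$p_max_neg)
    else
      anticorrelation_filter(pairs, recs, mode = "matched_samples",
                             mirna_values = rna$mirna$values,
                             rna_values = log_norm,
                             p_max_neg = config$p_max_neg)
  })
  network <- run_stage("network", build_network(triplets))
  hubs <- hub_scores(network)
  persist(triplets, "triplets"); persist(hubs, "hub_scores")
  if (!is.null(out_dir))
    write_sif(network, file.path(out_dir, "network.sif"))
  stage_log(verbose, "network: %d nodes, %d edges",
            nrow(network$nodes), nrow(network$edges))

  # -- enrichment (optional) --------------------------------------------
  enrich <- NULL
  if (!is.null(collection)) {
    net_mrnas <- network$nodes$id[network$nodes$class == "mRNA"]
    if (length(net_mrnas))
      enrich <- run_stage("enrichment", {
        bg <- unique(unlist(if (inherits(collection, "gene_set_collection"))
          collection$sets else collection))
        ora(intersect(net_mrnas, bg), collection, ease = config$ease)
      })
    if (!is.null(enrich)) persist(enrich, "enrichment")
  }

  # -- survival ----------------------------------------------------------
  flags <- run_stage("survival", cnv_deficiency_table(
    cnv$segments, hub_lncrna_exons(), threshold = config$cnv_threshold))
  screen <- run_stage("survival", screen_covariates(
    cnv$clinical, endpoint = "os", alpha = config$screen_alpha))
  sel <- screen$covariate[screen$selected]
  cox_os <- run_stage("survival",
                      cox_multivariate(cnv$clinical, flags, sel, "os"))
  cox_dfs <- run_stage("survival",
                       cox_multivariate(cnv$clinical, flags, sel, "dfs"))
  persist(cox_os, "cox_os"); persist(cox_dfs, "cox_dfs")

  node_tab <- table(factor(network$nodes$class, c("lncRNA", "miRNA", "mRNA")))
  manifest <- list(
    parameters = unclass(config),
    counts = list(
      n_demis_per_cohort = vapply(passing, nrow, 0L),
      n_demis_consensus = length(demis),
      n_demis_final = length(pruned$kept),
      n_dels = length(merged$dels),
      n_dems = length(merged$dems),
      n_pairs = nrow(pairs),
      n_triplets = nrow(triplets),
      n_nodes = as.list(node_tab),
      n_edges = nrow(network$edges)),
    hub_table = hubs,
    screen = screen)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest[c("parameters", "counts")],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(manifest = manifest,
       results = list(de_mirna = de_mir, consensus = demis,
                      de_rna = de_rna, de_rna_passing = de_pass,
                      records = merged$records, pruned = pruned,
                      pairs = pairs, triplets = triplets, network = network,
                      hubs = hubs, enrichment = enrich,
                      cnv_flags = flags, cox_os = cox_os, cox_dfs = cox_dfs,
                      truth = list(mirna = mir$truth, rna = rna$truth,
                                   cnv = cnv$truth)))
}
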