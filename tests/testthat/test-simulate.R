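test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(sponge_rho = 1.2), "sponge_rho")
  expect_error(sim_config(anti_rho = 0.5), "anti_rho")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(true_vote_range = c(4, 9)), "vote ranges")
  expect_error(sim_config(n_mirnas = 0), "counts")
  expect_error(sim_config(cnv_del_fraction = 1.5), "cnv_del_fraction")
})

test_that("all generators are byte-identical under the same seed", {
  cfg <- sim_config(seed = 11)
  a <- simulate_mirna_cohorts(cfg); b <- simulate_mirna_cohorts(cfg)
  expect_identical(a, b)
  r1 <- simulate_rnaseq_cohort(cfg); r2 <- simulate_rnaseq_cohort(cfg)
  expect_identical(r1$rna$values, r2$rna$values)
  expect_identical(simulate_target_table(cfg, r1$truth),
                   simulate_target_table(cfg, r2$truth))
  expect_identical(simulate_cnv_and_survival(cfg),
                   simulate_cnv_and_survival(cfg))
})

test_that("null miRNA effect produces no planted shift", {
  cfg <- sim_config(seed = 3, de_log2fc = 0, n_planted_triplets = 0,
                    n_decoy_mirnas = 0)
  sim <- simulate_mirna_cohorts(cfg)
  expect_length(sim$truth$planted_mirnas, 0)
  co <- sim$cohorts[[1]]
  diffs <- rowMeans(co$values[, co$groups == "tumour"]) -
    rowMeans(co$values[, co$groups == "benign"])
  # pure noise: mean difference should be near zero for every miRNA
  se <- sqrt(1 / sum(co$groups == "tumour") + 1 / sum(co$groups == "benign"))
  expect_true(all(abs(diffs) < 5 * se))
})

test_that("planted miRNA shift matches de_log2fc within sampling error", {
  cfg <- sim_config(seed = 5, de_log2fc = 3,
                    mirna_cohorts = list(c(20, 20), c(20, 20), c(20, 20)))
  sim <- simulate_mirna_cohorts(cfg)
  se <- sqrt(1 / 20 + 1 / 20)  # unit noise sd by construction
  for (i in 1:3) {
    co <- sim$cohorts[[i]]
    shifted <- sim$truth$de_mirnas_by_cohort[[i]]
    shifted <- intersect(shifted, sim$truth$planted_mirnas)
    if (!length(shifted)) next
    diffs <- rowMeans(co$values[shifted, co$groups == "benign", drop = FALSE]) -
      rowMeans(co$values[shifted, co$groups == "tumour", drop = FALSE])
    expect_true(all(abs(diffs - 3) < 3 * se))
  }
})

test_that("planted miRNAs are shifted in >=2 cohorts and decoys in exactly 1", {
  sim <- simulate_mirna_cohorts(sim_config(seed = 21))
  appearances <- table(unlist(sim$truth$de_mirnas_by_cohort))
  for (m in sim$truth$planted_mirnas)
    expect_gte(unname(appearances[m]), 2)
  for (m in sim$truth$decoy_mirnas)
    expect_equal(unname(appearances[m]), 1)
})

test_that("planted pairs exceed the coexpression cutoff in >=90% of cases", {
  hits <- 0; total <- 0
  for (seed in 1:25) {
    sim <- simulate_rnaseq_cohort(sim_config(seed = seed))
    vals <- log2(normalize_counts(sim$rna)$values + 1)
    tr <- sim$truth$triplets
    r <- vapply(seq_len(nrow(tr)), function(i)
      cor(vals[tr$lncrna_id[i], ], vals[tr$mrna_id[i], ]), 0)
    hits <- hits + sum(r > 0.4); total <- total + length(r)
  }
  expect_gte(total, 200)
  expect_gte(hits / total, 0.9)
})

test_that("planted correlations converge to sponge_rho and anti_rho at large n", {
  cfg <- sim_config(seed = 8, n_benign_rna = 250, n_tumor_rna = 250,
                    rna_de_log2fc = 0, nb_dispersion = 0.001)
  sim <- simulate_rnaseq_cohort(cfg)
  vals <- log2(normalize_counts(sim$rna)$values + 1)
  tr <- sim$truth$triplets
  pair_r <- vapply(seq_len(nrow(tr)), function(i)
    cor(vals[tr$lncrna_id[i], ], vals[tr$mrna_id[i], ]), 0)
  anti_r <- vapply(seq_len(nrow(tr)), function(i)
    cor(vals[tr$lncrna_id[i], ], sim$mirna$values[tr$mirna_id[i], ]), 0)
  # latent targets; NB sampling and miRNA measurement noise attenuate the
  # observed values slightly, within the +-0.05 design tolerance
  expect_lt(abs(mean(pair_r) - 0.9), 0.05)
  expect_lt(abs(mean(anti_r) - (-0.8)), 0.05)
})

test_that("target tables honor the vote ranges and the truth set", {
  cfg <- sim_config(seed = 13, true_vote_range = c(7, 7))
  tr <- simulate_rnaseq_cohort(cfg)$truth
  tab <- simulate_target_table(cfg, tr)
  nv <- vapply(strsplit(tab$programs, ","), function(p) length(unique(p)), 0L)
  planted <- paste(tr$triplets$mirna_id, tr$triplets$lncrna_id) |>
    c(paste(tr$triplets$mirna_id, tr$triplets$mrna_id))
  is_planted <- paste(tab$mirna_id, tab$target_id) %in% planted
  expect_true(all(nv[is_planted] == 7))
  expect_true(all(nv[!is_planted] <= 3))
  # default ranges: vote filtering on all classes recovers exactly the truth
  cfg2 <- sim_config(seed = 13)
  tab2 <- simulate_target_table(cfg2, tr)
  kept <- vote_filter(tab2, 4, apply_to = c("mRNA", "lncRNA"))
  expect_setequal(paste(kept$mirna_id, kept$target_id), planted)
  # empty truth: decoys only
  tab3 <- simulate_target_table(cfg, NULL)
  expect_true(all(vapply(strsplit(tab3$programs, ","), length, 0L) <= 7))
  expect_false(any(paste(tab3$mirna_id, tab3$target_id) %in% planted &
                     vapply(strsplit(tab3$programs, ","), length, 0L) > 3))
})

test_that("ground-truth ids always exist in the emitted artifacts", {
  cfg <- sim_config(seed = 17)
  mir <- simulate_mirna_cohorts(cfg)
  rna <- simulate_rnaseq_cohort(cfg)
  expect_true(all(mir$truth$planted_mirnas %in% rownames(mir$cohorts[[1]]$values)))
  expect_true(all(rna$truth$triplets$lncrna_id %in% rownames(rna$rna$values)))
  expect_true(all(rna$truth$triplets$mrna_id %in% rownames(rna$rna$values)))
  expect_true(all(rna$truth$triplets$mirna_id %in% rownames(rna$mirna$values)))
  cs <- simulate_cnv_and_survival(cfg)
  for (g in names(cs$truth$deficient_patients))
    expect_true(all(cs$truth$deficient_patients[[g]] %in% cs$clinical$patient_id))
})

test_that("cnv_del_fraction = 0 yields no deficient call downstream", {
  cs <- simulate_cnv_and_survival(sim_config(seed = 4, cnv_del_fraction = 0))
  flags <- cnv_deficiency_table(cs$segments, hub_lncrna_exons())
  expect_false(any(as.matrix(flags[, -1])))
})

test_that("null hazard gives comparable survival in both CNV groups", {
  ps <- vapply(1:5, function(s) {
    cs <- simulate_cnv_and_survival(sim_config(seed = s, log_hr_deficient = 0,
                                               log_hr_stage = 0))
    def <- cs$clinical$patient_id %in% cs$truth$deficient_patients[[1]]
    m1 <- km_median(cs$clinical$os_months[def], cs$clinical$os_event[def])
    m2 <- km_median(cs$clinical$os_months[!def], cs$clinical$os_event[!def])
    expect_true(m1$defined && m2$defined)
    lr <- survival::survdiff(
      survival::Surv(cs$clinical$os_months, cs$clinical$os_event) ~ def)
    1 - pchisq(lr$chisq, 1)
  }, 0)
  # log-rank should look null in nearly all replicates
  expect_gte(sum(ps > 0.05), 4)
})

test_that("expression round-trips through the TSV writer and reader", {
  x <- toy_array(seed = 7)
  dir <- withr::local_tempdir()
  write_expression(x, file.path(dir, "m.tsv"), file.path(dir, "g.tsv"))
  y <- read_expression(file.path(dir, "m.tsv"), file.path(dir, "g.tsv"), "array")
  expect_equal(x$values, y$values, tolerance = 1e-12)
  expect_identical(x$groups, y$groups)
})

test_that("sim config YAML round-trip rejects unknown keys", {
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(seed = 9, n_mirnas = 30), file.path(dir, "ok.yaml"))
  cfg <- read_sim_config(file.path(dir, "ok.yaml"))
  expect_equal(cfg$n_mirnas, 30)
  expect_equal(cfg$seed, 9L)
  yaml::write_yaml(list(seed = 9, bogus = 1), file.path(dir, "bad.yaml"))
  expect_error(read_sim_config(file.path(dir, "bad.yaml")), "bogus")
})
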