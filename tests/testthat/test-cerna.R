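test_that("pearson_with_p agrees with the direct formula oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  res <- pearson_with_p(x, y)
  orc <- oracle_pearson(x, y)
  expect_equal(res$r, orc$r, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- pearson_with_p(x, y)
    orc <- oracle_pearson(x, y)
    expect_equal(res$r, orc$r, tolerance = 1e-12)
    expect_equal(res$p, orc$p, tolerance = 1e-12)
  }
})

test_that("pearson_with_p handles identity, antisymmetry and degeneracy", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, x)$p, 0)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_error(pearson_with_p(x, rep(2, 5), id_b = "flatgene"), "flatgene")
  expect_error(pearson_with_p(x, c(1, 2)), "equal length")
  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "n >= 3")
})

test_that("pearson r is affine-invariant and sign-flips under negation", {
  set.seed(42)
  x <- rnorm(20); y <- rnorm(20)
  base <- pearson_with_p(x, y)
  shifted <- pearson_with_p(3 * x + 7, 0.5 * y - 2)
  expect_equal(base$r, shifted$r, tolerance = 1e-12)
  expect_equal(base$p, shifted$p, tolerance = 1e-12)
  expect_equal(pearson_with_p(-x, y)$r, -base$r, tolerance = 1e-12)
})

test_that("coexpression pairs use strict cutoffs and match a double loop", {
  # a pair sitting exactly at the r_min cutoff is excluded (strict >)
  x <- c(1, 2, 3, 4, 5, 6)
  y <- 0.4 * x + 0.6 * c(6, 1, 5, 2, 4, 3)
  lnc <- matrix(x, 1, dimnames = list("L1", sprintf("s%d", 1:6)))
  mrna <- matrix(y, 1, dimnames = list("M1", sprintf("s%d", 1:6)))
  at_cutoff <- stats::cor(t(lnc), t(mrna))[1, 1]
  expect_gt(at_cutoff, 0)
  expect_equal(nrow(coexpression_pairs(lnc, mrna, r_min = at_cutoff,
                                       p_max = 0.99)), 0)
  expect_equal(nrow(coexpression_pairs(lnc, mrna,
                                       r_min = at_cutoff - 1e-12,
                                       p_max = 0.99)), 1)

  set.seed(43)
  lnc <- matrix(rnorm(100), 10, 10,
                dimnames = list(sprintf("L%d", 1:10), sprintf("s%d", 1:10)))
  mrna <- matrix(rnorm(100), 10, 10,
                 dimnames = list(sprintf("M%d", 1:10), sprintf("s%d", 1:10)))
  got <- coexpression_pairs(lnc, mrna, r_min = 0.2, p_max = 0.5)
  brute <- list()
  for (i in 1:10) for (j in 1:10) {
    orc <- oracle_pearson(lnc[i, ], mrna[j, ])
    if (orc$r > 0.2 && orc$p < 0.5)
      brute[[length(brute) + 1]] <- sprintf("L%d-M%d", i, j)
  }
  expect_setequal(paste(got$lncrna_id, got$mrna_id, sep = "-"),
                  unlist(brute))
  bad <- mrna; colnames(bad) <- rev(colnames(mrna))
  expect_error(coexpression_pairs(lnc, bad), "share sample columns")
})

test_that("a planted high-correlation pair passes the default cutoffs", {
  sim <- simulate_rnaseq_cohort(sim_config(seed = 44))
  vals <- log2(normalize_counts(sim$rna)$values + 1)
  tr <- sim$truth$triplets[1, ]
  got <- coexpression_pairs(vals[tr$lncrna_id, , drop = FALSE],
                            vals[tr$mrna_id, , drop = FALSE])
  expect_equal(nrow(got), 1)
})

test_that("de_direction mode forms triplets only under sign opposition", {
  pairs <- data.frame(lncrna_id = "L1", mrna_id = "M1", r = 0.8, p = 1e-5,
                      stringsAsFactors = FALSE)
  recs <- data.frame(mirna_id = c("R1", "R1"), target_id = c("L1", "M1"),
                     target_class = c("lncRNA", "mRNA"), programs = "A,B,C,D",
                     stringsAsFactors = FALSE)
  up_down_down <- anticorrelation_filter(
    pairs, recs, mode = "de_direction",
    mirna_log2fc = c(R1 = 2), gene_log2fc = c(L1 = -1.5, M1 = -2))
  expect_equal(nrow(up_down_down), 1)
  expect_true(all(up_down_down$lnc_mirna_assoc < 0))
  up_up <- anticorrelation_filter(
    pairs, recs, mode = "de_direction",
    mirna_log2fc = c(R1 = 2), gene_log2fc = c(L1 = 1.5, M1 = -2))
  expect_equal(nrow(up_up), 0)
  # no common miRNA targeting both members: no triplet
  solo <- recs[1, , drop = FALSE]
  expect_equal(nrow(anticorrelation_filter(
    pairs, solo, mode = "de_direction",
    mirna_log2fc = c(R1 = 2), gene_log2fc = c(L1 = -1, M1 = -1))), 0)
})

test_that("matched-samples mode recovers planted triplets accurately", {
  stats <- t(vapply(1:10, function(seed) {
    cfg <- sim_config(seed = seed)
    sim <- simulate_rnaseq_cohort(cfg)
    tab <- simulate_target_table(cfg, sim$truth)
    vals <- log2(normalize_counts(sim$rna)$values + 1)
    voted <- vote_filter(tab, 4, apply_to = c("mRNA", "lncRNA"))
    pairs <- coexpression_pairs(
      vals[sim$truth$planted_lncrnas, , drop = FALSE],
      vals[sim$truth$planted_mrnas, , drop = FALSE])
    tri <- anticorrelation_filter(pairs, voted, mode = "matched_samples",
                                  mirna_values = sim$mirna$values,
                                  rna_values = vals)
    key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
    truth <- key(sim$truth$triplets)
    c(recall = mean(truth %in% key(tri)),
      precision = if (nrow(tri)) mean(key(tri) %in% truth) else NA_real_)
  }, c(recall = 0, precision = 0)))
  expect_gte(median(stats[, "recall"]), 0.9)
  expect_gte(median(stats[, "precision"], na.rm = TRUE), 0.9)
})

test_that("matched-samples mode demands shared samples", {
  pairs <- data.frame(lncrna_id = "L1", mrna_id = "M1", r = 0.8, p = 1e-5)
  recs <- data.frame(mirna_id = c("R1", "R1"), target_id = c("L1", "M1"),
                     target_class = c("lncRNA", "mRNA"), programs = "A,B,C,D")
  mir <- matrix(rnorm(5), 1, dimnames = list("R1", sprintf("a%d", 1:5)))
  rna <- matrix(rnorm(10), 2, dimnames = list(c("L1", "M1"), sprintf("b%d", 1:5)))
  expect_error(anticorrelation_filter(pairs, recs, mode = "matched_samples",
                                      mirna_values = mir, rna_values = rna),
               "shared samples")
})

test_that("network assembly deduplicates edges and keeps provenance", {
  tri1 <- data.frame(lncrna_id = "L1", mirna_id = "R1", mrna_id = "M1",
                     pair_r = 0.9, pair_p = 0, lnc_mirna_assoc = -1,
                     mrna_mirna_assoc = -1, stringsAsFactors = FALSE)
  net1 <- build_network(tri1)
  expect_equal(nrow(net1$nodes), 3)
  expect_equal(nrow(net1$edges), 2)
  tri2 <- rbind(tri1, within(tri1, mrna_id <- "M2"))
  net2 <- build_network(tri2)   # shared (L1, R1) edge counted once
  expect_equal(nrow(net2$nodes), 4)
  expect_equal(nrow(net2$edges), 3)
  clash <- rbind(tri1, data.frame(lncrna_id = "M1", mirna_id = "R2",
                                  mrna_id = "X", pair_r = 0.9, pair_p = 0,
                                  lnc_mirna_assoc = -1, mrna_mirna_assoc = -1))
  expect_error(build_network(clash), "conflicting")
})

test_that("node/edge counts equal brute-force set construction", {
  set.seed(46)
  for (i in 1:100) {
    tri <- random_triplets(sample(1:25, 1))
    net <- build_network(tri)
    orc <- oracle_network_counts(tri)
    expect_equal(nrow(net$nodes), orc$n_nodes)
    expect_equal(nrow(net$edges), orc$n_edges)
  }
})

test_that("removing triplets never adds edges (monotone)", {
  set.seed(47)
  tri <- random_triplets(30)
  full <- build_network(tri)
  sub <- build_network(tri[1:10, ])
  expect_true(all(paste(sub$edges$from, sub$edges$to) %in%
                    paste(full$edges$from, full$edges$to)))
})

test_that("hub scores reproduce the pair-count definition", {
  # hub with 9 distinct miRNAs and 200 distinct miRNA-mRNA pairs totals 209
  tri <- do.call(rbind, lapply(1:9, function(i) {
    mr <- sprintf("M%d_%d", i, 1:23)[seq_len(if (i <= 2) 23 else 22)]
    data.frame(lncrna_id = "HUB", mirna_id = sprintf("R%d", i), mrna_id = mr,
               pair_r = 0.9, pair_p = 0, lnc_mirna_assoc = -1,
               mrna_mirna_assoc = -1, stringsAsFactors = FALSE)
  }))
  expect_equal(nrow(unique(tri[, c("mirna_id", "mrna_id")])), 200)
  hs <- hub_scores(build_network(tri))
  expect_equal(hs$n_lnc_mirna_pairs, 9)
  expect_equal(hs$n_mirna_mrna_pairs, 200)
  expect_equal(hs$total, 209)
})

test_that("hub scores equal a brute-force recount; absent lncRNA scores 0", {
  set.seed(48)
  for (i in 1:100) {
    tri <- random_triplets(sample(1:25, 1))
    hs <- hub_scores(build_network(tri))
    for (j in seq_len(nrow(hs))) {
      orc <- oracle_hub(tri, hs$lncrna_id[j])
      expect_equal(hs$n_lnc_mirna_pairs[j], unname(orc["n_mir"]))
      expect_equal(hs$n_mirna_mrna_pairs[j], unname(orc["n_mm"]))
      expect_equal(hs$total[j], unname(orc["total"]))
    }
    expect_false(is.unsorted(-hs$total))
  }
  expect_equal(nrow(hub_scores(build_network(random_triplets(0)))), 0)
})

test_that("subnetwork edges equal the hub's total pair score", {
  # 2 miRNAs, 3 distinct mRNAs each: 1 + 2 + 6 nodes and 2 + 6 = 8 edges
  tri <- data.frame(lncrna_id = "HUB", mirna_id = rep(c("R1", "R2"), each = 3),
                    mrna_id = sprintf("M%d", 1:6), pair_r = 0.9, pair_p = 0,
                    lnc_mirna_assoc = -1, mrna_mirna_assoc = -1,
                    stringsAsFactors = FALSE)
  net <- build_network(tri)
  sub <- extract_subnetwork(net, "HUB")
  expect_equal(nrow(sub$nodes), 9)
  expect_equal(nrow(sub$edges), 8)
  expect_error(extract_subnetwork(net, "nope"), "unknown lncRNA")
  set.seed(49)
  for (i in 1:25) {
    tri <- random_triplets(sample(1:25, 1))
    net <- build_network(tri)
    hs <- hub_scores(net)
    for (L in hs$lncrna_id)
      expect_equal(nrow(extract_subnetwork(net, L)$edges),
                   hs$total[hs$lncrna_id == L])
  }
})

test_that("network exports round-trip through SIF and GraphML", {
  tri <- random_triplets(8)
  net <- build_network(tri)
  dir <- withr::local_tempdir()
  write_sif(net, file.path(dir, "n.sif"))
  sif <- read.table(file.path(dir, "n.sif"), sep = "\t")
  expect_equal(nrow(sif), nrow(net$edges))
  expect_setequal(unique(sif$V2), unique(net$edges$type))
  write_graphml(net, file.path(dir, "n.graphml"))
  g <- igraph::read_graph(file.path(dir, "n.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(igraph::vertex_attr(g, "class"), unique(net$nodes$class))
  write_edgelist(net, file.path(dir, "n.tsv"))
  expect_equal(nrow(read.table(file.path(dir, "n.tsv"), header = TRUE)),
               nrow(net$edges))
})
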