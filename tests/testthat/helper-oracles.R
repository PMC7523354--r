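# Independent brute-force oracles, kept deliberately naive (loops and
# first-principles formulas) so they cannot share defects with the package
# implementations they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  r <- num / den
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (j in i:n) vals <- c(vals, p[ord[j]] * n / j)
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

oracle_vote_filter <- function(records, min_programs, apply_to = "mRNA") {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    nv <- length(unique(strsplit(records$programs[i], ",")[[1]]))
    keep[i] <- if (records$target_class[i] %in% apply_to) nv >= min_programs
               else TRUE
  }
  records[keep, , drop = FALSE]
}

oracle_consensus <- function(sets, min_cohorts) {
  ids <- unique(unlist(sets))
  out <- character(0)
  for (id in ids) {
    cnt <- 0
    for (s in sets) if (id %in% s) cnt <- cnt + 1
    if (cnt >= min_cohorts) out <- c(out, id)
  }
  sort(out)
}

oracle_network_counts <- function(triplets) {
  nodes <- unique(c(triplets$lncrna_id, triplets$mirna_id, triplets$mrna_id))
  e1 <- unique(paste(triplets$lncrna_id, triplets$mirna_id))
  e2 <- unique(paste(triplets$mirna_id, triplets$mrna_id))
  list(n_nodes = length(nodes), n_edges = length(e1) + length(e2))
}

oracle_hub <- function(triplets, lnc) {
  mirs <- character(0); mm <- character(0)
  for (i in seq_len(nrow(triplets))) {
    if (triplets$lncrna_id[i] != lnc) next
    mirs <- union(mirs, triplets$mirna_id[i])
    mm <- union(mm, paste(triplets$mirna_id[i], triplets$mrna_id[i]))
  }
  c(n_mir = length(mirs), n_mm = length(mm), total = length(mirs) + length(mm))
}

oracle_cnv_call <- function(segments, exons, threshold = -0.3) {
  strip <- function(ch) sub("^chr", "", tolower(ch))
  patients <- unique(segments$sample)
  out <- logical(length(patients)); names(out) <- patients
  for (p in patients) {
    seg <- segments[segments$sample == p, , drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(seg))) {
      if (seg$seg_mean[i] > threshold) next
      for (j in seq_len(nrow(exons))) {
        if (strip(seg$chromosome[i]) != strip(exons$chromosome[j])) next
        if (max(seg$start[i], exons$start[j]) <= min(seg$end[i], exons$end[j]))
          hit <- TRUE
      }
    }
    out[p] <- hit
  }
  out
}

# exhaustive hypergeometric upper tail P(X >= k)
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  total <- 0
  for (j in k:min(K, n))
    total <- total + choose(K, j) * choose(N - K, n - j)
  total / choose(N, n)
}

seg_row <- function(sample, chrom, start, end, mean)
  data.frame(sample = sample, chromosome = chrom, start = start, end = end,
             num_probes = 10L, seg_mean = mean, stringsAsFactors = FALSE)

# small random prediction table for vote-filter fuzzing
random_prediction_table <- function(n_rows, programs = LETTERS[1:7]) {
  data.frame(
    mirna_id = sample(sprintf("mir-%d", 1:5), n_rows, replace = TRUE),
    target_id = sprintf("t-%d", seq_len(n_rows)),
    target_class = sample(c("mRNA", "lncRNA"), n_rows, replace = TRUE),
    programs = vapply(seq_len(n_rows), function(i)
      paste(sample(programs, sample(1:7, 1)), collapse = ","), ""),
    stringsAsFactors = FALSE)
}

random_triplets <- function(n) {
  data.frame(
    lncrna_id = sample(sprintf("L%d", 1:4), n, replace = TRUE),
    mirna_id = sample(sprintf("R%d", 1:5), n, replace = TRUE),
    mrna_id = sample(sprintf("M%d", 1:8), n, replace = TRUE),
    pair_r = runif(n, 0.5, 1), pair_p = runif(n, 0, 0.01),
    lnc_mirna_assoc = -runif(n), mrna_mirna_assoc = -runif(n),
    stringsAsFactors = FALSE)
}

# tiny two-group array matrix
toy_array <- function(n_feat = 5, n_ben = 4, n_tum = 4, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_feat * (n_ben + n_tum), 8), n_feat,
                 dimnames = list(sprintf("f%d", 1:n_feat),
                                 sprintf("s%d", 1:(n_ben + n_tum))))
  expr_matrix(vals, c(rep("benign", n_ben), rep("tumour", n_tum)), "array")
}
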