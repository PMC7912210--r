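# Shared fixtures and independent oracles, built in code.

# tibble from a genes x samples matrix with generated sample ids
tbl_mat <- function(m, id = "gene", prefix = "S") {
  colnames(m) <- sprintf("%s%02d", prefix, seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(!!id := sprintf("G%03d", seq_len(nrow(m)))), out)
  out
}

sheet_for <- function(m, n_case, prefix = "S") {
  n <- ncol(m)
  tibble::tibble(sample = sprintf("%s%02d", prefix, seq_len(n)),
                 group = rep(c("case", "control"), c(n_case, n - n_case)))
}

# brute-force Benjamini-Hochberg step-up: p_(i) * n / i with a cumulative
# minimum from the largest p downwards, capped at 1
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * n / seq_len(n)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(n)
  out[o] <- pmin(adj_sorted, 1)
  out
}

# exact upper-tail hypergeometric by direct binomial-coefficient enumeration
hyper_tail_enum <- function(k, K, N, n) {
  ks <- seq(max(0, k), min(K, n))
  if (k <= max(0, n - (N - K))) return(1)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# all-pairs counting AUC oracle, ties counted one half
auc_pairs <- function(scores, is_case) {
  cs <- scores[is_case]
  ct <- scores[!is_case]
  total <- 0
  for (a in cs) for (b in ct) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cs) * length(ct))
}

# trapezoidal integration of the empirical ROC curve
auc_trapezoid <- function(scores, is_case) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- vapply(thr, function(t) mean(scores[!is_case] >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(scores[is_case] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# small deterministic annotation: one CpG per region per gene
flat_annotation <- function(n_genes = 1, n_intergenic = 0) {
  simulate_annotation(n_genes, n_intergenic,
                      regions_per_gene = list(TSS1500 = 1, TSS200 = 1, `5UTR` = 1,
                                              `1stExon` = 1, Body = 1, `3UTR` = 1),
                      seed = 1)
}

# beta tibble from explicit per-probe values replicated across samples
beta_from_values <- function(probe_ids, values, sample_ids) {
  m <- matrix(rep(values, length(sample_ids)), nrow = length(probe_ids))
  colnames(m) <- sample_ids
  dplyr::bind_cols(tibble::tibble(probe_id = probe_ids), tibble::as_tibble(m))
}

# default-conditions cohort shared by the heavier stochastic tests;
# built lazily once per test run
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_config(seed = 101L))
    cache
  }
})

# run the differential-methylation stage of a cohort
run_dm_stage <- function(co, alpha = 0.05) {
  gene_beta <- aggregate_gene_beta(co$beta, co$annotation)
  intergenic <- co$beta[co$beta$probe_id %in%
                          co$annotation$probe_id[co$annotation$region == "Intergenic"], ]
  call_dmgs(gene_beta, intergenic, co$samples, alpha = alpha)
}

# builds a gene x sample beta tibble with exact group-mean difference per
# gene: a symmetric +/- pattern keeps group means at (base, base + delta)
exact_delta_mat <- function(deltas, noise_amp, n_per_group = 4, base = 0.5) {
  pat <- rep(c(-1, 1), n_per_group / 2)
  m <- t(vapply(seq_along(deltas), function(i) {
    c(base + deltas[i] + pat * noise_amp[i], base + pat * noise_amp[i])
  }, numeric(2 * n_per_group)))
  m
}

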