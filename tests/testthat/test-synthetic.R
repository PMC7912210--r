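test_that("annotation generator honours counts, labels and determinism", {
  # one CpG in each of the six regions of a single gene
  ann <- flat_annotation(n_genes = 1)
  expect_equal(nrow(ann), 6)
  expect_setequal(ann$region, region_levels())
  expect_true(all(ann$gene == "G0001"))
  expect_false(anyDuplicated(ann$probe_id) > 0)

  # identical seeds give identical tables
  a1 <- simulate_annotation(100, 50, seed = 11)
  a2 <- simulate_annotation(100, 50, seed = 11)
  expect_identical(a1, a2)
  expect_equal(sum(a1$region == "Intergenic"), 50)
  expect_true(all(is.na(a1$gene[a1$region == "Intergenic"])))
  expect_true(all(!is.na(a1$gene[a1$region != "Intergenic"])))

  # forcing zero CpGs in 1stExon removes the label entirely
  spec <- default_region_spec()
  spec$`1stExon` <- 0
  a3 <- simulate_annotation(50, 0, regions_per_gene = spec, seed = 3)
  expect_false("1stExon" %in% a3$region)
  # every gene keeps at least one CpG
  expect_setequal(unique(a3$gene), sprintf("G%04d", 1:50))

  expect_error(simulate_annotation(0), class = "methdx_error_config")
  expect_error(simulate_annotation(5, -1), class = "methdx_error_config")
})

test_that("cohort generation is seed-deterministic with valid ranges", {
  cfg <- cohort_config(n_case = 10, n_control = 8, n_genes = 40,
                       n_intergenic_cpgs = 30, seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$truth, c2$truth)

  B <- as.matrix(c1$beta[, -1])
  expect_true(all(B >= 0 & B < 1))
  expect_true(all(is.finite(as.matrix(c1$expression[, -1]))))
  # truth covers every gene; non-intergenic probes map to one gene + region
  expect_setequal(c1$truth$gene, sprintf("G%04d", 1:40))
  genic <- c1$annotation[c1$annotation$region != "Intergenic", ]
  expect_true(all(genic$region %in% region_levels()))
})

test_that("planted truth counts follow the configured fractions", {
  co <- simulate_cohort(cohort_config(n_case = 5, n_control = 5, n_genes = 200,
                                      n_intergenic_cpgs = 0, frac_hypo_up = 0.1,
                                      frac_hyper_down = 0.15, seed = 9))
  expect_equal(sum(co$truth$is_hypo_up), 20)
  expect_equal(sum(co$truth$is_hyper_down), 30)
  expect_true(all(co$truth$n_affected_regions[co$truth$status != "null"] %in% 1:2))
  expect_true(all(co$truth$n_affected_regions[co$truth$status == "null"] == 0))

  # null cohort: both effects zero => no flagged genes
  nul <- simulate_cohort(cohort_config(n_case = 5, n_control = 5, n_genes = 50,
                                       delta_beta_effect = 0, log2fc_effect = 0,
                                       seed = 2))
  expect_equal(sum(nul$truth$status != "null"), 0)

  expect_error(cohort_config(frac_hypo_up = 0.7, frac_hyper_down = 0.5),
               class = "methdx_error_config")
  expect_error(cohort_config(delta_beta_effect = 0.5), class = "methdx_error_config")
  expect_error(cohort_config(n_case = 1), class = "methdx_error_config")
})

test_that("planted effect sizes are recovered by group means (Monte-Carlo)", {
  cfg <- cohort_config(n_case = 60, n_control = 60, n_genes = 150,
                       n_intergenic_cpgs = 50, log2fc_effect = 1.0,
                       expr_sd = 0.5, meth_penetrance = 1, seed = 77)
  co <- simulate_cohort(cfg)
  c_n <- 1 / cfg$n_case + 1 / cfg$n_control

  # expression: mean case-control log2 difference over hypo-up genes
  hypo <- co$truth$gene[co$truth$is_hypo_up]
  lfc <- group_delta_beta(co$expression[co$expression$gene %in% hypo, ], co$samples)
  se_lfc <- cfg$expr_sd * sqrt(c_n / length(hypo))
  expect_lt(abs(mean(lfc$delta_beta) - cfg$log2fc_effect), 3 * se_lfc)

  # methylation: mean delta-beta over the planted probes of hypo-up genes
  aff <- co$truth[co$truth$is_hypo_up, ]
  pairs <- tidyr::unnest(aff[, c("gene", "affected_regions")],
                         cols = "affected_regions")
  probes <- dplyr::inner_join(
    co$annotation, pairs,
    by = c(gene = "gene", region = "affected_regions")
  )$probe_id
  pb <- group_delta_beta(co$beta[co$beta$probe_id %in% probes, ], co$samples)
  # shared sample offset does not average out across probes; subject-level
  # component averages over genes, probe noise over probes
  se_db <- sqrt(c_n * (cfg$sample_sd^2 + cfg$gene_sample_sd^2 / length(hypo) +
                         cfg$beta_dispersion^2 / length(probes)))
  expect_lt(abs(mean(pb$delta_beta) + cfg$delta_beta_effect), 3 * se_db)
})

test_that("methylation penetrance scales the observed group delta-beta", {
  cfg <- cohort_config(n_case = 80, n_control = 80, n_genes = 150,
                       n_intergenic_cpgs = 0, meth_penetrance = 0.6, seed = 55)
  co <- simulate_cohort(cfg)
  # carriers are a subset of cases
  expect_true(all(!co$samples$meth_carrier[co$samples$group == "control"]))
  flagged <- co$truth[co$truth$status == "hypo_up", ]
  pairs <- tidyr::unnest(flagged[, c("gene", "affected_regions")],
                         cols = "affected_regions")
  probes <- dplyr::inner_join(co$annotation, pairs,
                              by = c(gene = "gene", region = "affected_regions"))$probe_id
  pb <- group_delta_beta(co$beta[co$beta$probe_id %in% probes, ], co$samples)
  c_n <- 1 / cfg$n_case + 1 / cfg$n_control
  # binomial carrier sampling dominates the uncertainty of the mean shift
  se <- sqrt(cfg$delta_beta_effect^2 * 0.6 * 0.4 / cfg$n_case +
               c_n * (cfg$sample_sd^2 + cfg$gene_sample_sd^2 / nrow(flagged) +
                        cfg$beta_dispersion^2 / length(probes)))
  expect_lt(abs(mean(pb$delta_beta) + 0.6 * cfg$delta_beta_effect), 3 * se)
})

test_that("split cohorts give expression its own sample set", {
  co <- simulate_cohort(cohort_config(n_case = 6, n_control = 6, n_genes = 20,
                                      split_cohorts = TRUE, seed = 4))
  expect_false(any(co$expression_samples$sample %in% co$samples$sample))
  expect_equal(table(co$expression_samples$group), table(co$samples$group))
  expect_setequal(setdiff(names(co$expression), "gene"), co$expression_samples$sample)
})
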