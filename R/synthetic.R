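#' Default CpG-count specification per gene region
#'
#' Each element is either a single fixed CpG count applied to every gene or a
#' `c(min, max)` integer range sampled uniformly per gene. The defaults give
#' roughly 12 CpGs per gene with the gene body carrying the most, mirroring
#' the relative probe density of 450K-style annotation.
#'
#' @return Named list over the six region labels.
#' @export
default_region_spec <- function() {
  list(TSS1500 = c(1, 3), TSS200 = c(1, 3), `5UTR` = c(0, 2),
       `1stExon` = c(0, 2), Body = c(2, 8), `3UTR` = c(0, 2))
}

#' Configuration for a synthetic case/control cohort
#'
#' Bundles all generator parameters with validation. Defaults describe the
#' study conditions used throughout the package's tests: 150 cases vs 75
#' controls, 200 genes, 500 intergenic CpGs, 10% hypo-up and 10% hyper-down
#' planted genes with negative methylation-expression coupling.
#'
#' @param n_case,n_control Sample counts per group (>= 2).
#' @param n_genes Number of genes (>= 1).
#' @param n_intergenic_cpgs Number of intergenic CpG probes (>= 0).
#' @param regions_per_gene Named list of CpG-count specs per region; see
#'   [default_region_spec()].
#' @param frac_hypo_up,frac_hyper_down Fractions of genes planted as
#'   hypo-methylated/up-regulated and hyper-methylated/down-regulated;
#'   their sum must be <= 1.
#' @param delta_beta_effect Magnitude of the planted beta shift, in beta
#'   units, applied in the affected region(s) of flagged genes; must lie in
#'   [0, 0.5).
#' @param log2fc_effect Magnitude of the planted expression shift (log2
#'   units).
#' @param expr_sd Per-sample expression noise SD (log2 units).
#' @param beta_dispersion Per-probe, per-sample technical beta noise SD.
#' @param sample_sd SD of a per-sample global methylation offset shared by
#'   every probe of that sample (emulates cell-composition variation).
#' @param gene_sample_sd SD of a per-(gene, sample) subject-level beta
#'   component shared by all CpGs of a gene in one sample.
#' @param meth_penetrance Fraction of case subjects that carry the planted
#'   methylation shift (subject-level, shared across a subject's flagged
#'   genes). Values below 1 emulate epigenetically heterogeneous disease:
#'   group-mean delta-beta scales by this fraction and no methylation
#'   classifier can exceed an AUC of `1 - (1 - meth_penetrance)/2`, while
#'   expression effects (full penetrance) remain fully separable.
#' @param coupling Sign convention of the methylation-expression coupling;
#'   only `"negative"` is supported.
#' @param split_cohorts If `TRUE`, expression samples form an independent
#'   cohort (own sample ids and noise) instead of sharing the methylation
#'   samples, mimicking studies whose two assays come from disjoint cohorts.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `methdx_config` list.
#' @export
cohort_config <- function(n_case = 150, n_control = 75, n_genes = 200,
                          n_intergenic_cpgs = 500,
                          regions_per_gene = default_region_spec(),
                          frac_hypo_up = 0.1, frac_hyper_down = 0.1,
                          delta_beta_effect = 0.2, log2fc_effect = 1.0,
                          expr_sd = 0.5, beta_dispersion = 0.04,
                          sample_sd = 0.04, gene_sample_sd = 0.02,
                          meth_penetrance = 0.7,
                          coupling = "negative", split_cohorts = FALSE,
                          seed = 1L) {
  for (nm in c("n_case", "n_control", "n_genes")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop_methdx(sprintf("`%s` must be a positive integer.", nm), "methdx_error_config")
    }
  }
  if (n_case < 2 || n_control < 2) {
    stop_methdx("`n_case` and `n_control` must each be >= 2.", "methdx_error_config")
  }
  if (!is.numeric(n_intergenic_cpgs) || n_intergenic_cpgs < 0) {
    stop_methdx("`n_intergenic_cpgs` must be >= 0.", "methdx_error_config")
  }
  if (frac_hypo_up < 0 || frac_hyper_down < 0 || frac_hypo_up + frac_hyper_down > 1) {
    stop_methdx("effect fractions must be >= 0 and sum to <= 1.", "methdx_error_config")
  }
  if (delta_beta_effect < 0 || delta_beta_effect >= 0.5) {
    stop_methdx("`delta_beta_effect` must lie in [0, 0.5).", "methdx_error_config")
  }
  if (meth_penetrance < 0 || meth_penetrance > 1) {
    stop_methdx("`meth_penetrance` must lie in [0, 1].", "methdx_error_config")
  }
  if (!identical(coupling, "negative")) {
    stop_methdx("only `coupling = \"negative\"` is supported.", "methdx_error_config")
  }
  for (nm in c("log2fc_effect", "expr_sd", "beta_dispersion", "sample_sd", "gene_sample_sd")) {
    if (get(nm) < 0) stop_methdx(sprintf("`%s` must be >= 0.", nm), "methdx_error_config")
  }
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_genes = as.integer(n_genes), n_intergenic_cpgs = as.integer(n_intergenic_cpgs),
    regions_per_gene = regions_per_gene,
    frac_hypo_up = frac_hypo_up, frac_hyper_down = frac_hyper_down,
    delta_beta_effect = delta_beta_effect, log2fc_effect = log2fc_effect,
    expr_sd = expr_sd, beta_dispersion = beta_dispersion,
    sample_sd = sample_sd, gene_sample_sd = gene_sample_sd,
    meth_penetrance = meth_penetrance,
    coupling = coupling, split_cohorts = isTRUE(split_cohorts),
    seed = as.integer(seed)
  ), class = "methdx_config")
}

# Annotation generator shared by simulate_annotation() and simulate_cohort();
# assumes the RNG state is already set by the caller.
gen_annotation <- function(n_genes, n_intergenic, regions_per_gene) {
  regs <- region_levels()
  counts <- matrix(0L, nrow = n_genes, ncol = length(regs), dimnames = list(NULL, regs))
  for (r in regs) {
    sp <- regions_per_gene[[r]]
    if (is.null(sp)) sp <- 0
    if (any(sp < 0)) {
      stop_methdx(sprintf("negative CpG count specified for region %s.", r),
                  "methdx_error_config")
    }
    counts[, r] <- if (length(sp) == 1) {
      rep.int(as.integer(sp), n_genes)
    } else {
      resample(seq.int(sp[1], sp[2]), n_genes)
    }
  }
  # every gene must carry at least one CpG somewhere
  orphan <- rowSums(counts) == 0
  counts[orphan, "Body"] <- 1L
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  long <- tibble::tibble(
    gene = rep(rep(gene_ids, times = length(regs)), times = as.vector(counts)),
    region = rep(rep(regs, each = n_genes), times = as.vector(counts))
  )
  long <- dplyr::arrange(long, .data$gene,
                         factor(.data$region, levels = regs))
  if (n_intergenic > 0) {
    long <- dplyr::bind_rows(long, tibble::tibble(
      gene = NA_character_, region = rep("Intergenic", n_intergenic)
    ))
  }
  long$probe_id <- sprintf("cg%07d", seq_len(nrow(long)))
  dplyr::select(long, "probe_id", "gene", "region")
}

#' Generate a synthetic probe annotation table
#'
#' Assigns CpG probes to genes and region labels (plus intergenic probes),
#' with per-region CpG counts drawn from `regions_per_gene`.
#'
#' @inheritParams cohort_config
#' @param n_intergenic Number of intergenic probes.
#' @param seed Integer seed.
#' @return Tibble with columns `probe_id`, `gene`, `region`; intergenic rows
#'   have `gene = NA` and `region = "Intergenic"`.
#' @export
simulate_annotation <- function(n_genes, n_intergenic = 0,
                                regions_per_gene = default_region_spec(),
                                seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) {
    stop_methdx("`n_genes` must be a positive integer.", "methdx_error_config")
  }
  if (n_intergenic < 0) {
    stop_methdx("`n_intergenic` must be >= 0.", "methdx_error_config")
  }
  withr::with_seed(as.integer(seed),
                   gen_annotation(as.integer(n_genes), as.integer(n_intergenic),
                                  regions_per_gene))
}

#' Generate a paired case/control expression + methylation cohort
#'
#' Produces a full synthetic study with known planted truth: a log2
#' expression matrix, a beta matrix in [0, 1), a probe annotation, sample
#' sheets and a per-gene truth table. Flagged hypo-up genes receive a beta
#' shift of `-delta_beta_effect` in 1-2 randomly chosen regions (their
#' dominant regions) and an expression shift of `+log2fc_effect` in cases;
#' hyper-down genes the mirrored signs. The beta noise model combines a
#' bimodal per-probe baseline, a per-sample global offset, a subject-level
#' per-(gene, sample) component and probe-level noise, clipped into
#' [0, 1 - 1e-6].
#'
#' @param config A [cohort_config()] object.
#' @return A `methdx_cohort` list with elements `expression`, `beta`,
#'   `annotation`, `samples`, `expression_samples`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "methdx_config")) {
    stop_methdx("`config` must be created by cohort_config().", "methdx_error_config")
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    ann <- gen_annotation(cfg$n_genes, cfg$n_intergenic_cpgs, cfg$regions_per_gene)
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    n <- cfg$n_case + cfg$n_control
    samples <- tibble::tibble(
      sample = sprintf("S%03d", seq_len(n)),
      group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
    )

    # --- planted truth -----------------------------------------------------
    null_effects <- cfg$delta_beta_effect == 0 && cfg$log2fc_effect == 0
    n_hypo <- if (null_effects) 0L else as.integer(round(cfg$frac_hypo_up * cfg$n_genes))
    n_hyper <- if (null_effects) 0L else as.integer(round(cfg$frac_hyper_down * cfg$n_genes))
    flagged <- if (n_hypo + n_hyper > 0) {
      sample(gene_ids, n_hypo + n_hyper)
    } else {
      character(0)
    }
    hypo_genes <- flagged[seq_len(n_hypo)]
    hyper_genes <- setdiff(flagged, hypo_genes)

    gene_regions <- ann |>
      dplyr::filter(!is.na(.data$gene)) |>
      dplyr::distinct(.data$gene, .data$region)
    affected <- purrr::map(flagged, function(g) {
      regs <- gene_regions$region[gene_regions$gene == g]
      k <- min(length(regs), sample.int(2L, 1L))
      sort(regs[sample.int(length(regs), k)])
    })
    names(affected) <- flagged

    status <- rep("null", cfg$n_genes)
    names(status) <- gene_ids
    status[hypo_genes] <- "hypo_up"
    status[hyper_genes] <- "hyper_down"
    planted_db <- ifelse(status == "hypo_up", -cfg$delta_beta_effect,
                         ifelse(status == "hyper_down", cfg$delta_beta_effect, 0))
    planted_lfc <- ifelse(status == "hypo_up", cfg$log2fc_effect,
                          ifelse(status == "hyper_down", -cfg$log2fc_effect, 0))
    region_sets <- purrr::map(gene_ids, function(g) affected[[g]] %||% character(0))

    truth <- tibble::tibble(
      gene = gene_ids,
      status = unname(status),
      is_hypo_up = unname(status == "hypo_up"),
      is_hyper_down = unname(status == "hyper_down"),
      planted_delta_beta = unname(planted_db),
      planted_log2fc = unname(planted_lfc),
      affected_regions = region_sets,
      n_affected_regions = lengths(region_sets),
      dominant_region_set = region_sets
    )

    # --- beta matrix -------------------------------------------------------
    np <- nrow(ann)
    probe_gene <- ann$gene
    probe_affected <- !is.na(probe_gene) & probe_gene %in% flagged &
      purrr::map2_lgl(probe_gene, ann$region,
                      function(g, r) !is.na(g) && r %in% (affected[[g]] %||% character(0)))
    high_mode <- stats::runif(np) < 0.5
    baseline <- ifelse(high_mode, rbeta(np, 12, 2.5), rbeta(np, 2.5, 12))
    # differential probes start mid-range so the planted shift stays in [0,1)
    baseline[probe_affected] <- rbeta(sum(probe_affected), 10, 10)
    shift <- rep(0, np)
    shift[probe_affected] <- planted_db[match(probe_gene[probe_affected], gene_ids)]

    case_ind <- as.numeric(samples$group == "case")
    # subject-level penetrance: only a fraction of cases carries the
    # planted methylation shift, shared across that subject's flagged genes
    carrier <- case_ind * stats::rbinom(n, 1L, cfg$meth_penetrance)
    v <- rnorm(n, 0, cfg$sample_sd)                     # sample-level offset
    gene_index <- match(probe_gene, gene_ids)           # NA for intergenic
    u <- matrix(rnorm(cfg$n_genes * n, 0, cfg$gene_sample_sd), cfg$n_genes, n)
    B <- baseline + outer(shift, carrier) +
      matrix(v, np, n, byrow = TRUE) +
      matrix(rnorm(np * n, 0, cfg$beta_dispersion), np, n)
    genic <- !is.na(gene_index)
    B[genic, ] <- B[genic, ] + u[gene_index[genic], ]
    B <- pmin(pmax(B, 0), 1 - 1e-6)
    colnames(B) <- samples$sample
    beta <- dplyr::bind_cols(tibble::tibble(probe_id = ann$probe_id),
                             tibble::as_tibble(B))

    # --- expression matrix -------------------------------------------------
    expr_samples <- samples
    if (cfg$split_cohorts) {
      expr_samples <- tibble::tibble(
        sample = sprintf("E%03d", seq_len(n)),
        group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
      )
    }
    mu <- rnorm(cfg$n_genes, 7, 1.5)
    case_ind_e <- as.numeric(expr_samples$group == "case")
    E <- mu + outer(planted_lfc, case_ind_e) +
      matrix(rnorm(cfg$n_genes * n, 0, cfg$expr_sd), cfg$n_genes, n)
    colnames(E) <- expr_samples$sample
    expression <- dplyr::bind_cols(tibble::tibble(gene = gene_ids),
                                   tibble::as_tibble(E))

    samples$meth_carrier <- carrier == 1
    structure(list(expression = expression, beta = beta, annotation = ann,
                   samples = samples, expression_samples = expr_samples,
                   truth = truth, config = cfg),
              class = "methdx_cohort")
  })
}

#' @export
print.methdx_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<methdx_cohort> %d case / %d control, %d genes, %d probes (%d intergenic)\n",
              cfg$n_case, cfg$n_control, cfg$n_genes, nrow(x$annotation),
              cfg$n_intergenic_cpgs))
  cat(sprintf("  planted: %d hypo-up, %d hyper-down (delta-beta %.3g, log2FC %.3g), seed %d\n",
              sum(x$truth$is_hypo_up), sum(x$truth$is_hyper_down),
              cfg$delta_beta_effect, cfg$log2fc_effect, cfg$seed))
  invisible(x)
}
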