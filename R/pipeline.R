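#' Write a tabular artifact with a metadata header
#'
#' TSV with header row, preceded by comment lines (`#key: value`) carrying
#' the package version, seed and configuration hash so every artifact is
#' self-describing.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, meta = list()) {
  header <- purrr::imap_chr(meta, function(v, k) sprintf("#%s: %s", k, v))
  readr::write_lines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a tabular artifact written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Tibble with the metadata lines in attribute `meta`.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readr::read_lines(path, n_max = 50L)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- NULL
  if (length(meta_lines) > 0) {
    kv <- strsplit(sub("^#", "", meta_lines), ": ", fixed = TRUE)
    meta <- stats::setNames(purrr::map_chr(kv, function(p) paste(p[-1], collapse = ": ")),
                            purrr::map_chr(kv, 1))
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(out, "meta") <- meta
  out
}

#' Pipeline configuration
#'
#' Collects every stage threshold, the classifier settings and the seed in
#' one validated object. The pipeline either simulates its inputs from a
#' [cohort_config()] or consumes user-supplied tables.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed recorded in every artifact header.
#' @param alpha_de,lfc DEG thresholds (adjusted p, |log2FC|).
#' @param alpha_dm DMG adjusted-p threshold.
#' @param deciles Pooled delta-beta quantile probabilities.
#' @param tol Dominant-region tolerance in beta units.
#' @param n_trees,classifier_seed Random-forest settings.
#' @param classify Run the three classifier views (default `TRUE`).
#' @param incremental Run full incremental feature selection (slow;
#'   default `FALSE` computes the all-gene LOO AUC per view).
#' @param cohort A [cohort_config()] to simulate inputs, or `NULL` when
#'   `inputs` are given.
#' @param inputs Optional named list of tibbles `expression`, `beta`,
#'   `annotation`, `samples` (and optionally `expression_samples`).
#' @param gmt Optional path to a GMT file; when given, over-representation
#'   of the hypo-up and hyper-down sets is tested against it.
#' @return A `methdx_pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, alpha_de = 0.05, lfc = 0.2,
                            alpha_dm = 0.05, deciles = c(0.1, 0.9), tol = 0.005,
                            n_trees = 500, classifier_seed = NULL,
                            classify = TRUE, incremental = FALSE,
                            cohort = cohort_config(seed = seed), inputs = NULL,
                            gmt = NULL) {
  if (any(c(alpha_de, alpha_dm) < 0) || any(c(alpha_de, alpha_dm) > 1)) {
    stop_methdx("alpha thresholds must lie in [0, 1].", "methdx_error_config")
  }
  if (lfc < 0 || tol < 0) {
    stop_methdx("`lfc` and `tol` must be >= 0.", "methdx_error_config")
  }
  if (length(deciles) != 2 || any(deciles < 0 | deciles > 1) || deciles[1] >= deciles[2]) {
    stop_methdx("`deciles` must be two increasing probabilities.", "methdx_error_config")
  }
  if (is.null(cohort) && is.null(inputs)) {
    stop_methdx("provide either `cohort` or `inputs`.", "methdx_error_config")
  }
  structure(list(outdir = outdir, seed = as.integer(seed), alpha_de = alpha_de,
                 lfc = lfc, alpha_dm = alpha_dm, deciles = deciles, tol = tol,
                 n_trees = n_trees, classifier_seed = classifier_seed %||% seed,
                 classify = isTRUE(classify), incremental = isTRUE(incremental),
                 cohort = cohort, inputs = inputs, gmt = gmt),
            class = "methdx_pipeline_config")
}

config_hash <- function(config) {
  digest::digest(config[setdiff(names(config), "outdir")], algo = "sha256")
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes simulate (when configured) -> differential expression ->
#' differential methylation -> dominant regions -> integration ->
#' optional enrichment -> the three classifier views, writing every stage
#' artifact under `config$outdir` with a metadata header and a manifest
#' JSON listing artifact checksums alongside the configuration snapshot.
#' When no genes survive integration the classification stage is skipped
#' with a warning.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with the stage results (`de`, `dm`,
#'   `dominant`, `groups`, `region_dist`, `classifiers`, ...) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "methdx_pipeline_config")) {
    stop_methdx("`config` must come from pipeline_config().", "methdx_error_config")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "methdx",
               version = as.character(utils::packageVersion("methdx")),
               seed = config$seed, config_hash = config_hash(config))
  artifacts <- character(0)
  emit <- function(x, name) {
    path <- file.path(config$outdir, name)
    write_matrix_tsv(x, path, meta)
    artifacts[[name]] <<- path
  }

  # --- inputs --------------------------------------------------------------
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    expression <- inp$expression; beta <- inp$beta
    annotation <- inp$annotation; samples <- inp$samples
    expression_samples <- inp$expression_samples %||% samples
    truth <- NULL
  } else {
    cohort <- simulate_cohort(config$cohort)
    expression <- cohort$expression; beta <- cohort$beta
    annotation <- cohort$annotation; samples <- cohort$samples
    expression_samples <- cohort$expression_samples
    truth <- cohort$truth
    emit(expression, "expression.tsv")
    emit(beta, "beta.tsv")
    emit(annotation, "annotation.tsv")
    emit(samples, "samples.tsv")
  }

  # --- differential expression --------------------------------------------
  de <- fit_moderated_de(expression, expression_samples,
                         alpha = config$alpha_de, lfc = config$lfc)
  degs <- call_degs(de, alpha = config$alpha_de, lfc = config$lfc)
  emit(tidy(de), "de_table.tsv")

  # --- differential methylation -------------------------------------------
  gene_beta <- aggregate_gene_beta(beta, annotation)
  intergenic <- beta[beta$probe_id %in%
                       annotation$probe_id[annotation$region == "Intergenic"], ,
                     drop = FALSE]
  dm <- call_dmgs(gene_beta, intergenic, samples,
                  alpha = config$alpha_dm, deciles = config$deciles)
  dmgs <- call_sets(dm)
  emit(tibble::as_tibble(dm), "dm_table.tsv")

  region_beta <- aggregate_region_beta(beta, annotation)
  region_delta <- group_delta_beta(region_beta, samples)

  # --- dominant regions ----------------------------------------------------
  dominant <- list()
  for (dir in c("hypo", "hyper")) {
    called <- dm$gene[dm$call == dir]
    if (length(called) > 0) {
      dominant[[dir]] <- find_dominant_regions(
        region_delta[region_delta$gene %in% called, , drop = FALSE],
        direction = dir, tol = config$tol
      )
    }
  }
  dominant_all <- dplyr::bind_rows(dominant, .id = "direction")
  if (nrow(dominant_all) > 0) emit(dominant_all, "dominant_regions.tsv")

  # --- integration ----------------------------------------------------------
  groups <- intersect_groups(degs$up, degs$down, dmgs$hypo, dmgs$hyper)
  emit(tidy(groups), "groups.tsv")
  region_calls <- region_dmg_calls(region_delta, attr(dm, "thresholds"))
  grouped_genes <- unique(unlist(unclass(groups), use.names = FALSE))
  region_dist <- NULL
  if (length(grouped_genes) > 0 &&
      all(grouped_genes %in% region_calls$gene)) {
    region_dist <- region_distribution(groups, region_calls)
    emit(region_dist, "region_distribution.tsv")
  }

  # --- enrichment (optional) ------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$gmt)) {
    collection <- read_gmt(config$gmt, universe = de$gene)
    enrichment <- purrr::map(
      list(hypo_up = groups$hypo_up, hyper_down = groups$hyper_down),
      function(g) if (length(g) > 0) ora_hypergeometric(g, collection) else NULL
    )
    for (nm in names(enrichment)) {
      if (!is.null(enrichment[[nm]])) emit(enrichment[[nm]], sprintf("ora_%s.tsv", nm))
    }
  }

  # --- classification -------------------------------------------------------
  classifiers <- NULL
  signature <- sort(c(groups$hypo_up, groups$hyper_down))
  if (config$classify && length(signature) >= 2) {
    dominant_tbl <- dominant_all[, c("gene", "region"), drop = FALSE]
    views <- list(
      expression = build_feature_view("expression", signature,
                                      expression = expression),
      beta_all_regions = build_feature_view("beta_all_regions", signature,
                                            beta = beta, annotation = annotation),
      beta_dominant_regions = build_feature_view("beta_dominant_regions", signature,
                                                 beta = beta, annotation = annotation,
                                                 dominant = dominant_tbl)
    )
    classifiers <- purrr::imap(views, function(v, nm) {
      smp <- if (nm == "expression") expression_samples else samples
      if (config$incremental) {
        incremental_selection(v, smp, seed = config$classifier_seed,
                              n_trees = config$n_trees)
      } else {
        sc <- loo_scores(v, smp, seed = config$classifier_seed,
                         n_trees = config$n_trees)
        a <- roc_auc(sc)
        list(kind = v$kind, loo_scores = sc, auc = a$auc, auc_p = a$p_value)
      }
    })
    auc_tbl <- purrr::map_dfr(classifiers, function(cl) {
      tibble::tibble(kind = cl$kind, auc = cl$auc, auc_p = cl$auc_p,
                     best_k = if (!is.null(cl$best_k)) cl$best_k else NA_integer_)
    })
    emit(auc_tbl, "classifier_auc.tsv")
  } else if (config$classify) {
    rlang::warn("fewer than 2 signature genes; classification stage skipped.")
  }

  manifest <- list(
    package = "methdx", version = meta$version, seed = config$seed,
    config_hash = meta$config_hash,
    artifacts = purrr::imap(artifacts, function(p, nm) {
      list(file = nm, sha256 = digest::digest(p, algo = "sha256", file = TRUE))
    })
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(de = de, degs = degs, dm = dm, dominant = dominant,
                 groups = groups, region_dist = region_dist,
                 enrichment = enrichment, classifiers = classifiers,
                 truth = truth, manifest = manifest,
                 manifest_path = manifest_path))
}

#' Verify a pipeline manifest against the files on disk
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @return Tibble `file`, `ok`; an error of class `methdx_error_integrity`
#'   is raised when any checksum mismatches.
#' @export
verify_manifest <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  outdir <- dirname(manifest_path)
  res <- purrr::map_dfr(manifest$artifacts, function(a) {
    path <- file.path(outdir, a$file)
    ok <- file.exists(path) &&
      identical(digest::digest(path, algo = "sha256", file = TRUE), a$sha256)
    tibble::tibble(file = a$file, ok = ok)
  })
  if (!all(res$ok)) {
    stop_methdx(sprintf("checksum mismatch for: %s",
                        paste(res$file[!res$ok], collapse = ", ")),
                "methdx_error_integrity")
  }
  res
}
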