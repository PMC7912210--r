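#' Beta value from methylated/unmethylated intensities
#'
#' beta = M / (M + U + a). The offset `a` (default 100) stabilises the ratio
#' when both intensities are small and keeps beta strictly below 1.
#'
#' @param M,U Non-negative methylated / unmethylated signal intensities
#'   (vectorised, recycled).
#' @param a Non-negative stabilising offset, default 100.
#' @return Beta values in [0, 1).
#' @export
compute_beta <- function(M, U, a = 100) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE) || any(a < 0)) {
    stop_methdx("intensities and offset must be non-negative.", "methdx_error_domain")
  }
  denom <- M + U + a
  if (any(denom <= 0, na.rm = TRUE)) {
    stop_methdx("M + U + a must be positive.", "methdx_error_domain")
  }
  M / denom
}

check_beta_annotation <- function(beta, annotation) {
  if (!"probe_id" %in% names(beta)) {
    stop_methdx("`beta` must have a `probe_id` column.", "methdx_error_config")
  }
  if (!all(c("probe_id", "gene", "region") %in% names(annotation))) {
    stop_methdx("`annotation` needs columns probe_id, gene, region.", "methdx_error_config")
  }
  genic <- annotation[!is.na(annotation$gene) & annotation$region != "Intergenic", ]
  missing <- setdiff(unique(genic$probe_id), beta$probe_id)
  if (length(missing) > 0) {
    rlang::warn(sprintf("%d annotated probe(s) absent from the beta matrix; skipped.",
                        length(missing)))
    genic <- genic[!genic$probe_id %in% missing, ]
  }
  if (nrow(genic) == 0) {
    stop_methdx("annotation shares no probes with the beta matrix.",
                "methdx_error_empty")
  }
  genic
}

#' Mean beta per gene region
#'
#' Unweighted arithmetic mean of the member CpG beta values for every
#' (gene, region, sample) combination. Intergenic probes are excluded and
#' (gene, region) pairs without CpGs are absent from the result rather than
#' zero. A probe annotated to several genes contributes to each of them.
#'
#' @param beta Tibble with `probe_id` plus one numeric column per sample.
#' @param annotation Tibble with columns `probe_id`, `gene`, `region`.
#' @return Tibble with columns `gene`, `region`, `n_cpgs`, then one column
#'   per sample.
#' @export
aggregate_region_beta <- function(beta, annotation) {
  genic <- check_beta_annotation(beta, annotation)
  sample_ids <- setdiff(names(beta), "probe_id")
  joined <- dplyr::inner_join(genic, beta, by = "probe_id")
  out <- joined |>
    dplyr::group_by(.data$gene, .data$region) |>
    dplyr::summarise(n_cpgs = dplyr::n(),
                     dplyr::across(dplyr::all_of(sample_ids), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene, factor(.data$region, levels = region_levels()))
  out
}

#' Mean beta per gene over all regions
#'
#' Mean of the beta values of every CpG annotated to a gene, regardless of
#' region. A CpG annotated to k genes contributes to each of the k means.
#'
#' @inheritParams aggregate_region_beta
#' @return Tibble with columns `gene`, `n_cpgs`, then one column per sample.
#' @export
aggregate_gene_beta <- function(beta, annotation) {
  genic <- check_beta_annotation(beta, annotation)
  sample_ids <- setdiff(names(beta), "probe_id")
  joined <- dplyr::inner_join(dplyr::distinct(genic, .data$probe_id, .data$gene),
                              beta, by = "probe_id")
  joined |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_cpgs = dplyr::n(),
                     dplyr::across(dplyr::all_of(sample_ids), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene)
}
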