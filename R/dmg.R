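#' Call differentially methylated genes by the pooled decile rule
#'
#' Computes gene-level delta-beta (case minus control) for every gene and
#' every intergenic CpG, pools the two delta-beta vectors, and takes the
#' empirical 0.1 and 0.9 quantiles of the pooled vector (linear-interpolation
#' definition, R quantile type 7) as the hypo/hyper thresholds. A gene is
#' called hypo-methylated iff its delta-beta falls strictly below the lower
#' threshold AND its BH-adjusted p-value from a two-group equal-variance
#' linear model on gene-level beta is below `alpha`; hyper-methylated is the
#' mirrored rule at the upper threshold.
#'
#' @param gene_beta Gene-level beta tibble (`gene`, optional `n_cpgs`, one
#'   column per sample), e.g. from [aggregate_gene_beta()].
#' @param intergenic_beta Intergenic CpG beta tibble (`probe_id` plus sample
#'   columns); may be `NULL` when no intergenic probes exist.
#' @param samples Sample sheet with columns `sample`, `group`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param deciles Pooled quantile probabilities, default `c(0.1, 0.9)`.
#' @param case Label of the case group.
#' @return A `methdx_dm` tibble with columns `gene`, `delta_beta`,
#'   `p_value`, `adj_p`, `call` (hypo/hyper/none); attributes `thresholds`
#'   (the two pooled quantiles) and `intergenic` (per-CpG delta-beta tibble).
#' @export
call_dmgs <- function(gene_beta, intergenic_beta = NULL, samples,
                      alpha = 0.05, deciles = c(0.1, 0.9), case = "case") {
  grp <- check_samples(samples, case = case)
  if (!"gene" %in% names(gene_beta)) {
    stop_methdx("`gene_beta` must have a `gene` column.", "methdx_error_config")
  }
  gene_db <- group_delta_beta(gene_beta, samples, case = case)
  inter_db <- NULL
  pooled <- gene_db$delta_beta
  if (!is.null(intergenic_beta) && nrow(intergenic_beta) > 0) {
    inter_db <- group_delta_beta(intergenic_beta, samples, case = case)
    pooled <- c(pooled, inter_db$delta_beta)
  }
  if (length(pooled) == 0) {
    stop_methdx("pooled delta-beta vector is empty.", "methdx_error_empty")
  }
  thresholds <- quantile(pooled, probs = deciles, type = 7, names = FALSE)

  m <- feature_matrix(gene_beta, c(grp$case_ids, grp$control_ids),
                      what = "gene-level beta matrix")
  st <- two_group_stats(m, grp$case_ids, grp$control_ids)
  se <- sqrt(st$s2 * (1 / st$n1 + 1 / st$n0))
  t_stat <- st$diff / se
  p <- 2 * pt(-abs(t_stat), st$d)
  p[!is.finite(t_stat)] <- NA_real_
  p[se == 0 & st$diff == 0] <- 1            # constant gene, no difference
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  adj <- bh_adjust(p)

  out <- tibble::tibble(
    gene = gene_beta$gene,
    delta_beta = gene_db$delta_beta,
    p_value = unname(p),
    adj_p = unname(adj),
    call = dplyr::case_when(
      gene_db$delta_beta < thresholds[1] & adj < alpha ~ "hypo",
      gene_db$delta_beta > thresholds[2] & adj < alpha ~ "hyper",
      TRUE ~ "none"
    )
  )
  structure(out, thresholds = thresholds, deciles = deciles, alpha = alpha,
            intergenic = inter_db, class = c("methdx_dm", class(out)))
}

#' Differentially methylated genes as sets
#'
#' @param dm A [call_dmgs()] result.
#' @return List with character vectors `hypo` and `hyper`.
#' @export
call_sets <- function(dm) {
  list(hypo = dm$gene[dm$call == "hypo"], hyper = dm$gene[dm$call == "hyper"])
}

#' @exportS3Method generics::glance
glance.methdx_dm <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble::tibble(
    n_genes = nrow(x),
    q_low = thr[1], q_high = thr[2],
    n_hypo = sum(x$call == "hypo"),
    n_hyper = sum(x$call == "hyper")
  )
}

#' Per-region differential methylation status
#'
#' Flags, for every (gene, region), whether the region-level delta-beta
#' falls beyond the pooled decile thresholds, giving the region-resolved
#' hypo/hyper status used for region-distribution tabulation.
#'
#' @param region_delta Tibble with columns `gene`, `region`, `delta_beta`
#'   (e.g. [group_delta_beta()] on [aggregate_region_beta()] output).
#' @param thresholds Length-2 numeric, the pooled lower/upper delta-beta
#'   thresholds (attribute `thresholds` of a [call_dmgs()] result).
#' @return Tibble `gene`, `region`, `delta_beta`, `call` restricted to
#'   regions called hypo or hyper.
#' @export
region_dmg_calls <- function(region_delta, thresholds) {
  if (!all(c("gene", "region", "delta_beta") %in% names(region_delta))) {
    stop_methdx("`region_delta` needs columns gene, region, delta_beta.",
                "methdx_error_config")
  }
  region_delta |>
    dplyr::mutate(call = dplyr::case_when(
      .data$delta_beta < thresholds[1] ~ "hypo",
      .data$delta_beta > thresholds[2] ~ "hyper",
      TRUE ~ "none"
    )) |>
    dplyr::filter(.data$call != "none") |>
    dplyr::select("gene", "region", "delta_beta", "call")
}

#' Dominant methylated regions
#'
#' For each gene, finds the region with the most extreme delta-beta in the
#' gene's direction of differential methylation (most negative for hypo,
#' most positive for hyper) and returns every region whose delta-beta lies
#' strictly within `tol` of that extreme — a gene can have several dominant
#' regions. `extreme = "signed-min"` instead always takes the smallest
#' signed delta-beta, the literal "smallest delta beta" reading. Ties at the
#' extreme are broken by the fixed region order of [region_levels()].
#'
#' @param region_delta Tibble with columns `gene`, `region`, `delta_beta`.
#' @param direction `"hypo"` or `"hyper"`.
#' @param tol Dominance tolerance in beta units (default 0.005, strict
#'   inequality).
#' @param extreme `"directional"` (default) or `"signed-min"`.
#' @return A `methdx_dominant` tibble with columns `gene`, `region`,
#'   `delta_beta`, `is_extreme`; attribute `tol`.
#' @export
find_dominant_regions <- function(region_delta, direction = c("hypo", "hyper"),
                                  tol = 0.005, extreme = c("directional", "signed-min")) {
  direction <- match.arg(direction)
  extreme <- match.arg(extreme)
  if (!all(c("gene", "region", "delta_beta") %in% names(region_delta))) {
    stop_methdx("`region_delta` needs columns gene, region, delta_beta.",
                "methdx_error_config")
  }
  rd <- dplyr::filter(region_delta, !is.na(.data$delta_beta))
  if (nrow(rd) == 0) {
    stop_methdx("no regions with a defined delta-beta.", "methdx_error_empty")
  }
  take_max <- direction == "hyper" && extreme == "directional"
  out <- rd |>
    dplyr::mutate(.region_rank = match(.data$region, region_levels())) |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      ext_val <- if (take_max) max(df$delta_beta) else min(df$delta_beta)
      at_ext <- which(df$delta_beta == ext_val)
      ext_row <- at_ext[order(df$.region_rank[at_ext])][1]
      keep <- abs(df$delta_beta - ext_val) < tol
      keep[ext_row] <- TRUE
      res <- df[keep, c("region", "delta_beta", ".region_rank")]
      res$is_extreme <- seq_len(nrow(df))[keep] == ext_row
      res
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene, .data$.region_rank) |>
    dplyr::select("gene", "region", "delta_beta", "is_extreme")
  structure(out, tol = tol, direction = direction, extreme = extreme,
            class = c("methdx_dominant", class(out)))
}

#' Dominant regions as a per-gene list
#'
#' @param dominant A [find_dominant_regions()] result.
#' @return Named list, gene -> character vector of dominant region labels.
#' @export
dominant_region_sets <- function(dominant) {
  split(dominant$region, dominant$gene)
}
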