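#' Canonical 450K-style gene region labels
#'
#' The six annotated gene regions used throughout the package, in the fixed
#' order that also breaks ties when two regions have identical delta-beta:
#' TSS1500, TSS200, 5UTR, 1stExon, Body, 3UTR. Probes outside any gene carry
#' the extra label `"Intergenic"`.
#'
#' @return Character vector of the six region labels.
#' @export
region_levels <- function() {
  c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
}

stop_methdx <- function(message, class) {
  rlang::abort(message, class = c(class, "methdx_error"))
}

# sample.int-based resample that never triggers sample()'s scalar surprise
resample <- function(x, n) {
  x[sample.int(length(x), n, replace = TRUE)]
}

#' @noRd
check_samples <- function(samples, case = "case", min_per_group = 2L) {
  if (!is.data.frame(samples) || !all(c("sample", "group") %in% names(samples))) {
    stop_methdx("`samples` must be a data frame with columns `sample` and `group`.",
                "methdx_error_config")
  }
  groups <- unique(as.character(samples$group))
  if (length(groups) != 2L) {
    stop_methdx(sprintf("`samples` must contain exactly 2 groups, found %d.", length(groups)),
                "methdx_error_config")
  }
  if (!case %in% groups) {
    stop_methdx(sprintf("case label '%s' not present in `samples$group`.", case),
                "methdx_error_config")
  }
  control <- setdiff(groups, case)
  case_ids <- samples$sample[samples$group == case]
  control_ids <- samples$sample[samples$group == control]
  if (length(case_ids) < min_per_group || length(control_ids) < min_per_group) {
    stop_methdx(sprintf("each group needs at least %d samples (found %d case, %d control).",
                        min_per_group, length(case_ids), length(control_ids)),
                "methdx_error_replication")
  }
  list(case = case, control = control, case_ids = as.character(case_ids),
       control_ids = as.character(control_ids))
}

# Extract the numeric sample-column matrix of a feature tibble
# (id columns first, one numeric column per sample).
feature_matrix <- function(x, sample_ids, what = "matrix") {
  missing <- setdiff(sample_ids, names(x))
  if (length(missing) > 0) {
    stop_methdx(sprintf("%s is missing %d sample column(s): %s", what, length(missing),
                        paste(head(missing, 5), collapse = ", ")),
                "methdx_error_config")
  }
  m <- as.matrix(x[, sample_ids, drop = FALSE])
  if (!is.numeric(m)) {
    stop_methdx(sprintf("sample columns of %s must be numeric.", what), "methdx_error_config")
  }
  m
}

#' Group delta-beta (case minus control)
#'
#' Computes the difference in group means, case minus control, for every row
#' of a feature table (gene-level beta, region-level beta, or intergenic CpG
#' beta). The sign convention makes hypo-methylation in cases a negative
#' delta-beta.
#'
#' @param x A tibble whose non-id columns are per-sample values; id columns
#'   are any of `probe_id`, `gene`, `region`.
#' @param samples Sample sheet with columns `sample`, `group`.
#' @param case Label of the case group (default `"case"`).
#' @return A tibble with the id columns of `x` plus `delta_beta`.
#' @export
group_delta_beta <- function(x, samples, case = "case") {
  grp <- check_samples(samples, case = case, min_per_group = 1L)
  id_cols <- intersect(c("probe_id", "gene", "region"), names(x))
  m <- feature_matrix(x, c(grp$case_ids, grp$control_ids), what = "feature table")
  delta <- rowMeans(m[, grp$case_ids, drop = FALSE]) -
    rowMeans(m[, grp$control_ids, drop = FALSE])
  out <- x[, id_cols, drop = FALSE]
  out$delta_beta <- unname(delta)
  tibble::as_tibble(out)
}
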