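#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around the step-up false-discovery-rate adjustment:
#' p-values are multiplied by n/rank and a cumulative minimum from the
#' largest p downwards enforces monotonicity. Output is order-preserving
#' with the input indexing and never smaller than the input.
#'
#' @param p_values Numeric vector of p-values, all in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop_methdx("all p-values must lie in (0, 1].", "methdx_error_domain")
  }
  p.adjust(p_values, method = "BH")
}

# Per-gene two-group summary statistics on a genes x samples matrix.
# Returns means, pooled variance and residual df; shared by the moderated
# t and the gene-level beta linear model.
two_group_stats <- function(m, case_ids, control_ids) {
  n1 <- length(case_ids)
  n0 <- length(control_ids)
  m1 <- rowMeans(m[, case_ids, drop = FALSE])
  m0 <- rowMeans(m[, control_ids, drop = FALSE])
  ss1 <- rowSums((m[, case_ids, drop = FALSE] - m1)^2)
  ss0 <- rowSums((m[, control_ids, drop = FALSE] - m0)^2)
  d <- n1 + n0 - 2L
  list(diff = m1 - m0, s2 = (ss1 + ss0) / d, d = d, n1 = n1, n0 = n0)
}

# Moments estimator of the prior df d0 and prior variance s0^2 of the
# scaled-F model for per-gene sample variances: if s^2 ~ s0^2 * F(d, d0),
#   E[s^2]        = s0^2 * d0 / (d0 - 2)
#   Var[s^2]/E^2  = 2 (d + d0 - 2) / (d (d0 - 4)).
# Solving the second relation for d0 and substituting back gives s0^2.
# When the observed variance of s^2 is at or below the value implied by
# d0 = Inf, the prior is treated as infinitely informative (s2_post = s0^2).
estimate_prior <- function(s2, d) {
  m <- mean(s2)
  v <- var(s2)
  if (!is.finite(v) || v <= 0 || m <= 0) {
    return(list(d0 = Inf, s0_sq = m))
  }
  r <- v / m^2
  if (r * d <= 2) {
    return(list(d0 = Inf, s0_sq = m))
  }
  d0 <- (4 * r * d + 2 * d - 4) / (r * d - 2)
  if (!is.finite(d0) || d0 <= 2) {
    return(list(d0 = Inf, s0_sq = m))
  }
  list(d0 = d0, s0_sq = m * (d0 - 2) / d0)
}

#' Moderated two-group differential expression
#'
#' Fits, for every gene of a log2 expression matrix, the two-group linear
#' model case vs control with an empirical-Bayes variance moderation: the
#' posterior variance is \eqn{s^2_{post} = (d_0 s_0^2 + d s^2)/(d_0 + d)}
#' with prior df \eqn{d_0} and prior variance \eqn{s_0^2} estimated from the
#' ensemble of per-gene variances by the method of moments. The moderated t
#' is referred to a t distribution on \eqn{d + d_0} df (normal when
#' \eqn{d_0 = \infty}); with `moderate = FALSE` (\eqn{d_0 = 0}) the
#' statistic is exactly the ordinary pooled-variance two-sample t.
#'
#' @param expression Tibble with a `gene` id column and one numeric column
#'   per sample (log2 scale, already normalized).
#' @param samples Sample sheet tibble with columns `sample`, `group`.
#' @param moderate Use empirical-Bayes moderation (default `TRUE`).
#' @param case Label of the case group.
#' @param alpha,lfc Thresholds used to fill the `direction` column
#'   (BH-adjusted p < `alpha` and |log2 fold-change| > `lfc`, both strict).
#' @return A `methdx_de` tibble with columns `gene`, `log2fc`, `t_stat`,
#'   `p_value`, `adj_p`, `direction`, carrying attributes `d0`, `s0_sq`,
#'   `df_residual`.
#' @export
fit_moderated_de <- function(expression, samples, moderate = TRUE,
                             case = "case", alpha = 0.05, lfc = 0.2) {
  grp <- check_samples(samples, case = case)
  if (!"gene" %in% names(expression)) {
    stop_methdx("`expression` must have a `gene` column.", "methdx_error_config")
  }
  m <- feature_matrix(expression, c(grp$case_ids, grp$control_ids),
                      what = "expression matrix")
  rownames(m) <- expression$gene
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    rlang::warn(sprintf("dropping %d gene(s) with missing values.", sum(!keep)))
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0) {
    stop_methdx("no genes left after dropping missing values.", "methdx_error_config")
  }
  st <- two_group_stats(m, grp$case_ids, grp$control_ids)
  if (all(st$s2 == 0)) {
    stop_methdx("all genes have zero pooled variance; cannot fit.",
                "methdx_error_degenerate")
  }
  if (moderate) {
    prior <- estimate_prior(st$s2, st$d)
  } else {
    prior <- list(d0 = 0, s0_sq = NA_real_)
  }
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_sq, length(st$s2))
  } else if (prior$d0 == 0) {
    st$s2
  } else {
    (prior$d0 * prior$s0_sq + st$d * st$s2) / (prior$d0 + st$d)
  }
  se <- sqrt(s2_post * (1 / st$n1 + 1 / st$n0))
  t_stat <- st$diff / se
  df_total <- st$d + prior$d0
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_stat)) else 2 * pt(-abs(t_stat), df_total)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  adj <- bh_adjust(p)
  out <- tibble::tibble(
    gene = rownames(m),
    log2fc = unname(st$diff),
    t_stat = unname(t_stat),
    p_value = unname(p),
    adj_p = unname(adj),
    direction = dplyr::case_when(
      adj < alpha & st$diff > lfc ~ "up",
      adj < alpha & st$diff < -lfc ~ "down",
      TRUE ~ "none"
    )
  )
  structure(out, d0 = prior$d0, s0_sq = prior$s0_sq, df_residual = st$d,
            alpha = alpha, lfc = lfc,
            class = c("methdx_de", class(out)))
}

#' Call differentially expressed genes
#'
#' Applies the joint gate: BH-adjusted p < `alpha` and |log2 fold-change|
#' strictly greater than `lfc`. Up- and down-regulated sets are disjoint by
#' construction.
#'
#' @param table A [fit_moderated_de()] result (or any tibble with columns
#'   `gene`, `log2fc`, `adj_p`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 0.2).
#' @return List with character vectors `up` and `down`.
#' @export
call_degs <- function(table, alpha = 0.05, lfc = 0.2) {
  req <- c("gene", "log2fc", "adj_p")
  if (!all(req %in% names(table))) {
    stop_methdx("`table` needs columns gene, log2fc, adj_p.", "methdx_error_config")
  }
  list(
    up = table$gene[table$adj_p < alpha & table$log2fc > lfc],
    down = table$gene[table$adj_p < alpha & table$log2fc < -lfc]
  )
}

#' @exportS3Method generics::glance
glance.methdx_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    d0 = attr(x, "d0"),
    s0_sq = attr(x, "s0_sq"),
    df_residual = attr(x, "df_residual"),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down")
  )
}

#' @exportS3Method generics::tidy
tidy.methdx_de <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene", "log2fc", "t_stat", "p_value", "adj_p", "direction")])
}
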