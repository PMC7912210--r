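#' Build a classifier feature view
#'
#' Assembles the gene x sample feature matrix for one of the three
#' classifier families: `expression` (log2 expression), `beta_all_regions`
#' (mean beta over every CpG of the gene) or `beta_dominant_regions` (mean
#' beta over the CpGs of the gene's dominant region set only).
#'
#' @param kind One of `"expression"`, `"beta_all_regions"`,
#'   `"beta_dominant_regions"`.
#' @param genes Character vector of genes to include; genes without data in
#'   the requested view are dropped with a warning.
#' @param expression Expression tibble (`gene` + sample columns); required
#'   for the expression view.
#' @param beta Probe-level beta tibble (`probe_id` + sample columns);
#'   required for the two methylation views.
#' @param annotation Probe annotation (`probe_id`, `gene`, `region`).
#' @param dominant A [find_dominant_regions()] result (or any tibble with
#'   columns `gene`, `region`); required for the dominant-region view.
#' @return A `methdx_view` list with elements `kind`, `data` (gene x sample
#'   tibble), `genes`, `samples` (sample ids).
#' @export
build_feature_view <- function(kind = c("expression", "beta_all_regions",
                                        "beta_dominant_regions"),
                               genes, expression = NULL, beta = NULL,
                               annotation = NULL, dominant = NULL) {
  kind <- match.arg(kind)
  genes <- unique(as.character(genes))
  if (length(genes) == 0) {
    stop_methdx("`genes` is empty.", "methdx_error_empty")
  }
  if (kind == "expression") {
    if (is.null(expression)) {
      stop_methdx("expression view needs `expression`.", "methdx_error_config")
    }
    data <- expression[expression$gene %in% genes, , drop = FALSE]
  } else {
    if (is.null(beta) || is.null(annotation)) {
      stop_methdx("methylation views need `beta` and `annotation`.", "methdx_error_config")
    }
    ann <- annotation
    if (kind == "beta_dominant_regions") {
      if (is.null(dominant)) {
        stop_methdx("dominant-region view needs `dominant`.", "methdx_error_config")
      }
      ann <- dplyr::semi_join(annotation, dominant[, c("gene", "region")],
                              by = c("gene", "region"))
    }
    ann <- ann[!is.na(ann$gene) & ann$gene %in% genes, , drop = FALSE]
    if (nrow(ann) == 0) {
      stop_methdx("no CpGs available for the requested genes.", "methdx_error_empty")
    }
    data <- aggregate_gene_beta(beta, ann)
    data$n_cpgs <- NULL
  }
  dropped <- setdiff(genes, data$gene)
  if (length(dropped) > 0) {
    rlang::warn(sprintf("%s view: %d gene(s) without data dropped (%s%s).",
                        kind, length(dropped), paste(head(dropped, 5), collapse = ", "),
                        if (length(dropped) > 5) ", ..." else ""))
  }
  m <- as.matrix(data[, setdiff(names(data), "gene"), drop = FALSE])
  if (anyNA(m)) {
    stop_methdx("feature view contains missing values.", "methdx_error_config")
  }
  structure(list(kind = kind, data = tibble::as_tibble(data),
                 genes = data$gene, samples = setdiff(names(data), "gene")),
            class = "methdx_view")
}

# samples x features matrix + factor labels (control first, case second)
view_xy <- function(view, samples, case = "case", genes = NULL) {
  grp <- check_samples(samples, case = case, min_per_group = 1L)
  genes <- genes %||% view$genes
  missing <- setdiff(genes, view$genes)
  if (length(missing) > 0) {
    stop_methdx(sprintf("gene(s) absent from the %s view: %s", view$kind,
                        paste(head(missing, 5), collapse = ", ")),
                "methdx_error_config")
  }
  data <- view$data[match(genes, view$data$gene), , drop = FALSE]
  ids <- c(grp$case_ids, grp$control_ids)
  x <- t(feature_matrix(data, ids, what = "feature view"))
  colnames(x) <- genes
  y <- factor(ifelse(rownames(x) %in% grp$case_ids, grp$case, grp$control),
              levels = c(grp$control, grp$case))
  list(x = x, y = y, case = grp$case)
}

#' Random-forest feature importance ranking
#'
#' Fits a random forest on the full data set and ranks genes by ensemble
#' importance in descending order (mean decrease in node impurity by
#' default, permutation importance optionally), with ties broken by gene
#' symbol. With `n_repeats > 1` the importance is averaged over repeated
#' forest fits.
#'
#' @param view A [build_feature_view()] object.
#' @param samples Sample sheet with columns `sample`, `group`.
#' @param seed Integer seed making the ranking deterministic.
#' @param n_trees Trees per forest (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(G))`.
#' @param metric `"impurity"` (default) or `"permutation"`.
#' @param n_repeats Number of forest fits to average over (default 1).
#' @param case Label of the case group.
#' @return Tibble `gene`, `importance`, `scaled_importance`, `rank`,
#'   ordered by rank.
#' @export
rank_importance <- function(view, samples, seed = 1L, n_trees = 500,
                            mtry = NULL, metric = c("impurity", "permutation"),
                            n_repeats = 1L, case = "case") {
  metric <- match.arg(metric)
  xy <- view_xy(view, samples, case = case)
  if (length(unique(xy$y)) < 2) {
    stop_methdx("labels contain a single class.", "methdx_error_config")
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(xy$x))))
  imp <- withr::with_seed(as.integer(seed), {
    reps <- purrr::map(seq_len(n_repeats), function(i) {
      fit <- randomForest::randomForest(
        x = xy$x, y = xy$y, ntree = n_trees, mtry = mtry,
        importance = metric == "permutation"
      )
      col <- if (metric == "permutation") "MeanDecreaseAccuracy" else "MeanDecreaseGini"
      randomForest::importance(fit)[, col]
    })
    Reduce(`+`, reps) / n_repeats
  })
  out <- tibble::tibble(gene = colnames(xy$x), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$gene)
  out$scaled_importance <- scale_importance(out$importance)
  out$rank <- seq_len(nrow(out))
  out
}

#' Min-max importance scaling to [0, 100]
#'
#' scaled = 100 (x - min) / (max - min), the printed-score convention in
#' which the top-ranked feature scores 100.00 and the bottom-ranked 0.00.
#' All-equal input (including a single value) returns zeros with a warning.
#'
#' @param raw Numeric vector of raw importances (non-empty).
#' @return Numeric vector in [0, 100].
#' @export
scale_importance <- function(raw) {
  if (length(raw) == 0) {
    stop_methdx("`raw` must be non-empty.", "methdx_error_empty")
  }
  rng <- range(raw)
  if (diff(rng) == 0) {
    rlang::warn("all raw importances are equal; returning zeros.")
    return(rep(0, length(raw)))
  }
  # clamp to guard against floating-point spill just outside [0, 100]
  pmin(pmax(100 * (raw - rng[1]) / diff(rng), 0), 100)
}

#' Leave-one-out out-of-fold case probabilities
#'
#' For each of the n samples, trains a random forest on the other n - 1 and
#' records the left-out sample's predicted case probability; n models in
#' total, so no sample is ever scored by a model that saw it.
#'
#' @inheritParams rank_importance
#' @param genes Optional restriction of the view to these genes (e.g. the
#'   top-k of an importance ranking).
#' @return Tibble `sample`, `group`, `score` (out-of-fold case probability).
#' @export
loo_scores <- function(view, samples, seed = 1L, n_trees = 500, mtry = NULL,
                       genes = NULL, case = "case") {
  xy <- view_xy(view, samples, case = case, genes = genes)
  n <- nrow(xy$x)
  if (n < 3) {
    stop_methdx("leave-one-out needs at least 3 samples.", "methdx_error_config")
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(xy$x))))
  scores <- withr::with_seed(as.integer(seed), {
    purrr::map_dbl(seq_len(n), function(i) {
      ytr <- xy$y[-i]
      if (length(unique(ytr)) < 2) {
        stop_methdx("a leave-one-out training fold contains a single class.",
                    "methdx_error_config")
      }
      fit <- randomForest::randomForest(x = xy$x[-i, , drop = FALSE], y = ytr,
                                        ntree = n_trees, mtry = mtry)
      predict(fit, xy$x[i, , drop = FALSE], type = "prob")[, xy$case]
    })
  })
  tibble::tibble(sample = rownames(xy$x), group = as.character(xy$y), score = scores)
}

# internal Mann-Whitney AUC on raw vectors, ties counted one half
mann_whitney_auc <- function(scores, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with rank-sum p-value
#'
#' AUC is the Mann-Whitney statistic divided by n_case * n_control, with
#' ties counted one half — the probability that a random case scores above
#' a random control. The p-value against AUC = 0.5 comes from the two-sided
#' normal-approximated Wilcoxon rank-sum test of the scores between the two
#' classes.
#'
#' @param scores Either the tibble returned by [loo_scores()] (columns
#'   `group`, `score`) or a numeric vector of scores.
#' @param labels Group labels (required when `scores` is a vector).
#' @param case Label counted as positive class.
#' @return One-row tibble `auc`, `p_value`, `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels = NULL, case = "case") {
  if (is.data.frame(scores)) {
    labels <- scores$group
    scores <- scores$score
  }
  labels <- as.character(labels)
  is_case <- labels == case
  if (!any(is_case) || all(is_case)) {
    stop_methdx("both classes must be present.", "methdx_error_config")
  }
  auc <- mann_whitney_auc(scores, is_case)
  p <- suppressWarnings(
    wilcox.test(scores[is_case], scores[!is_case], exact = FALSE, correct = FALSE)$p.value
  )
  tibble::tibble(auc = auc, p_value = p,
                 n_case = sum(is_case), n_control = sum(!is_case))
}

#' Empirical ROC curve coordinates
#'
#' Step-function ROC of a score vector: one point per distinct threshold,
#' from (0, 0) to (1, 1). Trapezoidal integration of this curve equals the
#' Mann-Whitney AUC.
#'
#' @inheritParams roc_auc
#' @return Tibble `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels = NULL, case = "case") {
  if (is.data.frame(scores)) {
    labels <- scores$group
    scores <- scores$score
  }
  is_case <- as.character(labels) == case
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    fpr = purrr::map_dbl(thr, ~ mean(scores[!is_case] >= .x)),
    tpr = purrr::map_dbl(thr, ~ mean(scores[is_case] >= .x))
  )
}

#' Importance-ranked incremental feature selection under LOO
#'
#' Adds genes to the classifier one by one in order of importance: for
#' every k = 1..G the top-k genes are evaluated by leave-one-out AUC, and
#' the best k is the smallest k attaining the maximal AUC. By default the
#' ranking is computed once on the full data set and leave-one-out applies
#' to AUC estimation only (the published protocol, which leaks ranking
#' information into the folds); `nested = TRUE` instead re-ranks the
#' features inside every training fold for an unbiased estimate.
#'
#' @inheritParams rank_importance
#' @param ranking Optional precomputed [rank_importance()] tibble.
#' @param max_k Evaluate k = 1..max_k only (default: all genes).
#' @param nested Re-rank within each leave-one-out fold (default `FALSE`).
#' @return A `methdx_classifier` list: `kind`, `ranking`, `auc_by_k`
#'   (tibble `k`, `auc`), `best_k`, `loo_scores` (at `best_k`), `auc`,
#'   `auc_p`, `settings`.
#' @export
incremental_selection <- function(view, samples, ranking = NULL, seed = 1L,
                                  n_trees = 500, mtry = NULL, max_k = NULL,
                                  nested = FALSE, case = "case") {
  if (is.null(ranking) && !nested) {
    ranking <- rank_importance(view, samples, seed = seed, n_trees = n_trees,
                               case = case)
  }
  xy <- view_xy(view, samples, case = case)
  n <- nrow(xy$x)
  G <- ncol(xy$x)
  ks <- seq_len(min(max_k %||% G, G))

  if (!nested) {
    ordered_genes <- ranking$gene
    score_mat <- withr::with_seed(as.integer(seed), {
      vapply(ks, function(k) {
        gsel <- ordered_genes[seq_len(k)]
        purrr::map_dbl(seq_len(n), function(i) {
          fit <- randomForest::randomForest(
            x = xy$x[-i, gsel, drop = FALSE], y = xy$y[-i],
            ntree = n_trees, mtry = max(1L, floor(sqrt(k)))
          )
          predict(fit, xy$x[i, gsel, drop = FALSE], type = "prob")[, xy$case]
        })
      }, numeric(n))
    })
  } else {
    # rank within each training fold, then score the left-out sample per k
    score_mat <- withr::with_seed(as.integer(seed), {
      folds <- purrr::map(seq_len(n), function(i) {
        xtr <- xy$x[-i, , drop = FALSE]
        ytr <- xy$y[-i]
        fit_full <- randomForest::randomForest(x = xtr, y = ytr, ntree = n_trees,
                                               mtry = max(1L, floor(sqrt(G))))
        imp <- randomForest::importance(fit_full)[, "MeanDecreaseGini"]
        ord <- names(sort(imp, decreasing = TRUE))
        purrr::map_dbl(ks, function(k) {
          gsel <- ord[seq_len(k)]
          fit <- randomForest::randomForest(
            x = xtr[, gsel, drop = FALSE], y = ytr,
            ntree = n_trees, mtry = max(1L, floor(sqrt(k)))
          )
          predict(fit, xy$x[i, gsel, drop = FALSE], type = "prob")[, xy$case]
        })
      })
      do.call(rbind, folds)   # n x k
    })
    if (is.null(ranking)) {
      ranking <- rank_importance(view, samples, seed = seed, n_trees = n_trees,
                                 case = case)
    }
  }

  is_case <- xy$y == levels(xy$y)[2]
  auc_by_k <- tibble::tibble(
    k = ks,
    auc = vapply(seq_along(ks), function(j) mann_whitney_auc(score_mat[, j], is_case),
                 numeric(1))
  )
  best_k <- auc_by_k$k[which.max(auc_by_k$auc)]   # which.max takes smallest on ties
  best_scores <- tibble::tibble(sample = rownames(xy$x),
                                group = as.character(xy$y),
                                score = score_mat[, match(best_k, ks)])
  final <- roc_auc(best_scores, case = xy$case)
  structure(list(kind = view$kind, ranking = ranking, auc_by_k = auc_by_k,
                 best_k = best_k, loo_scores = best_scores,
                 auc = final$auc, auc_p = final$p_value,
                 settings = list(seed = as.integer(seed), n_trees = n_trees,
                                 nested = nested, case = xy$case)),
            class = "methdx_classifier")
}

#' @export
print.methdx_classifier <- function(x, ...) {
  cat(sprintf("<methdx_classifier> %s view: best k = %d, LOO AUC = %.3f (p = %.3g)\n",
              x$kind, x$best_k, x$auc, x$auc_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.methdx_classifier <- function(x, ...) {
  x$ranking
}

#' @exportS3Method generics::glance
glance.methdx_classifier <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_genes = nrow(x$ranking), best_k = x$best_k,
                 auc = x$auc, auc_p = x$auc_p,
                 n_samples = nrow(x$loo_scores))
}
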