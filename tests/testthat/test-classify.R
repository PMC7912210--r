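make_view <- function(m, prefix = "S") {
  build_feature_view("expression", sprintf("G%03d", seq_len(nrow(m))),
                     expression = tbl_mat(m, prefix = prefix))
}

test_that("importance scaling follows the min-max [0, 100] convention", {
  expect_equal(scale_importance(c(2, 4, 6)), c(0, 50, 100))
  expect_warning(s <- scale_importance(7), "equal")
  expect_equal(s, 0)
  expect_warning(s2 <- scale_importance(c(3, 3, 3)), "equal")
  expect_equal(s2, c(0, 0, 0))
  expect_error(scale_importance(numeric(0)), class = "methdx_error_empty")

  withr::with_seed(2, {
    for (i in 1:10) {
      x <- rnorm(sample(2:30, 1))
      s <- scale_importance(x)
      expect_equal(s[which.max(x)], 100)
      expect_equal(s[which.min(x)], 0)
      expect_true(all(s >= 0 & s <= 100))
    }
  })
})

test_that("forest importance recovers a separating feature deterministically", {
  withr::with_seed(19, {
    n <- 30
    m <- matrix(rnorm(10 * n), nrow = 10)
    labels <- rep(c("case", "control"), c(15, 15))
    m[4, ] <- ifelse(labels == "case", 2, -2) + rnorm(n, sd = 0.1)
    m[7, ] <- 1.5                          # constant feature
  })
  view <- make_view(m)
  sheet <- tibble::tibble(sample = sprintf("S%02d", 1:30),
                          group = rep(c("case", "control"), c(15, 15)))
  r1 <- rank_importance(view, sheet, seed = 5, n_trees = 200)
  expect_equal(r1$gene[1], "G004")
  expect_equal(r1$importance[r1$gene == "G007"], 0)
  expect_equal(r1$scaled_importance[1], 100)
  expect_equal(r1$scaled_importance[nrow(r1)], 0)
  # identical seed and input give the identical ranking
  r2 <- rank_importance(view, sheet, seed = 5, n_trees = 200)
  expect_identical(r1, r2)
  # single-class labels are rejected
  expect_error(rank_importance(view, dplyr::mutate(sheet, group = "case"), seed = 1),
               class = "methdx_error_config")
})

test_that("leave-one-out scoring holds out exactly one sample per model", {
  m <- rbind(c(5, 6, 1, 2), c(0.1, 0.2, 0.1, 0.3))
  view <- make_view(m)
  sheet <- sheet_for(m, 2)
  sc <- loo_scores(view, sheet, seed = 1, n_trees = 50)
  expect_equal(nrow(sc), 4)
  expect_setequal(sc$sample, sheet$sample)

  # a feature identical to the label separates perfectly: AUC 1
  withr::with_seed(23, {
    n <- 12
    lab <- rep(c("case", "control"), each = 6)
    m2 <- rbind(ifelse(lab == "case", 1, 0) + rnorm(n, sd = 0.01), rnorm(n))
  })
  view2 <- make_view(m2)
  sheet2 <- tibble::tibble(sample = sprintf("S%02d", 1:12), group = lab)
  sc2 <- loo_scores(view2, sheet2, seed = 2, n_trees = 100)
  expect_true(all(sc2$score[sc2$group == "case"] > 0.5))
  expect_true(all(sc2$score[sc2$group == "control"] < 0.5))
  expect_equal(roc_auc(sc2)$auc, 1)

  expect_error(loo_scores(make_view(m[, 1:2, drop = FALSE]), sheet_for(m[, 1:2], 1),
                          seed = 1),
               class = "methdx_error_config")
})

test_that("label-permuted leave-one-out AUC is centred on one half", {
  withr::with_seed(29, {
    n <- 20
    m <- matrix(rnorm(5 * n), nrow = 5)
    view <- make_view(m)
    aucs <- vapply(1:20, function(i) {
      sheet <- tibble::tibble(sample = sprintf("S%02d", 1:n),
                              group = sample(rep(c("case", "control"), each = n / 2)))
      roc_auc(loo_scores(view, sheet, seed = i, n_trees = 50))$auc
    }, numeric(1))
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs))
})

test_that("ROC AUC equals pair counting and trapezoidal integration", {
  # hand example with a tie: AUC = (1 + 0.5 + 2)/4
  res <- roc_auc(c(0.2, 0.4, 0.4, 0.8), c("control", "control", "case", "case"))
  expect_equal(res$auc, 0.875)

  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c("case", "case", "control", "control"))$auc, 1)

  withr::with_seed(37, {
    for (i in 1:40) {
      n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
      scores <- round(c(rnorm(n1, 0.5), rnorm(n0)), sample(c(1, 8), 1))  # force ties sometimes
      labels <- rep(c("case", "control"), c(n1, n0))
      is_case <- labels == "case"
      a <- roc_auc(scores, labels)$auc
      expect_equal(a, auc_pairs(scores, is_case), tolerance = 1e-10)
      expect_equal(a, auc_trapezoid(scores, is_case), tolerance = 1e-10)
      # swapping the class labels maps AUC to its complement
      swapped <- ifelse(labels == "case", "control", "case")
      expect_equal(roc_auc(scores, swapped)$auc, 1 - a, tolerance = 1e-10)
    }
  })

  # agreement with an established ROC implementation
  withr::with_seed(41, {
    scores <- rnorm(40)
    labels <- rep(c("case", "control"), each = 20)
    a <- roc_auc(scores, labels)$auc
    p <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("control", "case"),
                                        direction = "<", quiet = TRUE)))
    expect_equal(a, p, tolerance = 1e-10)
  })

  expect_error(roc_auc(c(0.1, 0.2), c("case", "case")), class = "methdx_error_config")
})

test_that("incremental selection tracks the argmax contract", {
  # G = 1: best k is 1
  m <- rbind(ifelse(rep(c(TRUE, FALSE), each = 5), 1, -1) + 0)
  view <- make_view(m)
  sheet <- sheet_for(m, 5)
  rep1 <- suppressWarnings(incremental_selection(view, sheet, seed = 3, n_trees = 50))
  expect_equal(rep1$best_k, 1)
  expect_equal(nrow(rep1$auc_by_k), 1)

  # informative gene at rank 1 among noise: early k already near-optimal
  withr::with_seed(43, {
    n <- 24
    lab <- rep(c("case", "control"), each = 12)
    m2 <- matrix(rnorm(6 * n), nrow = 6)
    m2[3, ] <- ifelse(lab == "case", 1.5, -1.5) + rnorm(n, sd = 0.3)
  })
  view2 <- make_view(m2)
  sheet2 <- tibble::tibble(sample = sprintf("S%02d", 1:24), group = lab)
  rep2 <- incremental_selection(view2, sheet2, seed = 7, n_trees = 100)
  expect_equal(rep2$ranking$gene[1], "G003")
  expect_equal(max(rep2$auc_by_k$auc), rep2$auc_by_k$auc[rep2$auc_by_k$k == rep2$best_k])
  expect_gte(rep2$auc_by_k$auc[1], rep2$auc_by_k$auc[nrow(rep2$auc_by_k)] - 0.1)
  expect_equal(rep2$auc, rep2$auc_by_k$auc[rep2$auc_by_k$k == rep2$best_k])
  # ties in the AUC curve resolve to the smallest k
  expect_equal(rep2$best_k, min(rep2$auc_by_k$k[rep2$auc_by_k$auc == max(rep2$auc_by_k$auc)]))

  # report accessors
  expect_s3_class(tidy(rep2), "tbl_df")
  g <- glance(rep2)
  expect_equal(g$best_k, rep2$best_k)

  # nested protocol re-ranks inside folds and still returns a full curve
  rep3 <- incremental_selection(view2, sheet2, seed = 7, n_trees = 50, max_k = 3,
                                nested = TRUE)
  expect_equal(nrow(rep3$auc_by_k), 3)
  expect_true(all(rep3$auc_by_k$auc >= 0 & rep3$auc_by_k$auc <= 1))
})

test_that("methylation feature views aggregate the right CpG sets", {
  ann <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3"),
    gene = c("G001", "G001", "G001"),
    region = c("TSS200", "Body", "Body")
  )
  beta <- beta_from_values(c("cg1", "cg2", "cg3"), c(0.1, 0.5, 0.7),
                           c("S01", "S02", "S03"))
  all_v <- build_feature_view("beta_all_regions", "G001", beta = beta, annotation = ann)
  expect_equal(all_v$data$S01, mean(c(0.1, 0.5, 0.7)))
  dom <- tibble::tibble(gene = "G001", region = "Body")
  dom_v <- build_feature_view("beta_dominant_regions", "G001", beta = beta,
                              annotation = ann, dominant = dom)
  expect_equal(dom_v$data$S01, 0.6)
  # genes without CpGs in the dominant set are dropped with a warning
  expect_warning(
    build_feature_view("beta_all_regions", c("G001", "G999"), beta = beta,
                       annotation = ann),
    "dropped"
  )
})
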