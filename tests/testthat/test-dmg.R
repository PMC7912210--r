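test_that("decile DMG rule matches exhaustive manual application on a toy", {
  deltas <- c(-0.20, -0.15, -0.12, -0.10, -0.06, -0.04, -0.02, -0.01, 0,
              0.005, 0.01, 0.02, 0.04, 0.06, 0.09, 0.11, 0.13, 0.15, 0.18, 0.20)
  noise <- rep(0.005, 20)
  noise[c(1, 19)] <- 0.45          # force non-significant p for two extremes
  m <- exact_delta_mat(deltas, noise)
  gene_beta <- tbl_mat(m)
  sheet <- sheet_for(m, 4)
  inter_deltas <- c(-0.03, -0.02, -0.01, 0, 0, 0.01, 0.02, 0.03, 0.04, -0.04)
  im <- exact_delta_mat(inter_deltas, rep(0.005, 10))
  intergenic <- tbl_mat(im, id = "probe_id")

  dm <- call_dmgs(gene_beta, intergenic, sheet, alpha = 0.05)

  # manual rule, recomputed from scratch: pooled deciles + independent t-tests
  pooled <- c(deltas, inter_deltas)
  q <- quantile(pooled, c(0.1, 0.9), type = 7, names = FALSE)
  p_manual <- vapply(seq_len(nrow(m)), function(i) {
    t.test(m[i, 1:4], m[i, 5:8], var.equal = TRUE)$p.value
  }, numeric(1))
  adj_manual <- bh_brute(p_manual)
  expected <- ifelse(deltas < q[1] & adj_manual < 0.05, "hypo",
                     ifelse(deltas > q[2] & adj_manual < 0.05, "hyper", "none"))
  expect_equal(dm$call, expected)
  expect_equal(dm$delta_beta, deltas, tolerance = 1e-12)
  expect_equal(attr(dm, "thresholds"), q, tolerance = 1e-12)
  # the two noisy extremes fail on p despite extreme delta-beta
  expect_equal(dm$call[c(1, 19)], c("none", "none"))
})

test_that("degenerate all-equal delta-beta yields zero calls", {
  m <- matrix(0.4, nrow = 6, ncol = 8)
  dm <- call_dmgs(tbl_mat(m), NULL, sheet_for(m, 4))
  expect_true(all(dm$call == "none"))
  expect_equal(unname(attr(dm, "thresholds")), c(0, 0))
})

test_that("pooled decile thresholds bound the tail fractions", {
  co <- default_cohort()
  dm <- run_dm_stage(co)
  pooled <- c(dm$delta_beta, attr(dm, "intergenic")$delta_beta)
  q <- attr(dm, "thresholds")
  n <- length(pooled)
  expect_lte(mean(pooled < q[1]), 0.1 + 1 / n)
  expect_lte(mean(pooled > q[2]), 0.1 + 1 / n)
})

test_that("dominant regions follow the tolerance rule", {
  rd <- tibble::tibble(gene = "GA",
                       region = c("TSS1500", "Body", "3UTR"),
                       delta_beta = c(-0.020, -0.024, -0.010))
  dom <- find_dominant_regions(rd, "hypo", tol = 0.005)
  expect_setequal(dom$region, c("TSS1500", "Body"))
  expect_equal(dom$region[dom$is_extreme], "Body")

  # boundary: exactly tol apart is excluded (strict <); binary-exact
  # values keep the equality test free of floating-point representation
  rd2 <- tibble::tibble(gene = "GA", region = c("Body", "TSS200"),
                        delta_beta = c(-5 * 2^-7, -4 * 2^-7))
  dom2 <- find_dominant_regions(rd2, "hypo", tol = 2^-7)
  expect_equal(dom2$region, "Body")

  # single region is trivially dominant
  rd3 <- tibble::tibble(gene = "GA", region = "5UTR", delta_beta = -0.01)
  expect_equal(find_dominant_regions(rd3, "hypo")$region, "5UTR")

  # hyper direction takes the most positive delta-beta
  rd4 <- tibble::tibble(gene = "GA", region = c("TSS1500", "Body", "3UTR"),
                        delta_beta = c(0.031, 0.010, 0.028))
  dom4 <- find_dominant_regions(rd4, "hyper", tol = 0.005)
  expect_setequal(dom4$region, c("TSS1500", "3UTR"))
  expect_equal(dom4$region[dom4$is_extreme], "TSS1500")

  # literal signed-minimum reading
  dom5 <- find_dominant_regions(rd4, "hyper", tol = 0.005, extreme = "signed-min")
  expect_equal(dom5$region, "Body")

  # ties at the extreme break by the fixed region order
  rd6 <- tibble::tibble(gene = "GA", region = c("Body", "TSS200"),
                        delta_beta = c(-0.02, -0.02))
  dom6 <- find_dominant_regions(rd6, "hypo", tol = 1e-9)
  expect_equal(dom6$region[dom6$is_extreme], "TSS200")

  expect_error(find_dominant_regions(rd3[0, ], "hypo"), class = "methdx_error_empty")
})

test_that("dominant sets are monotone in the tolerance and keep the extreme", {
  withr::with_seed(13, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      rd <- tibble::tibble(gene = "G", region = sample(region_levels(), k),
                          delta_beta = round(rnorm(k, 0, 0.02), 4))
      tols <- sort(runif(3, 0.001, 0.04))
      sets <- lapply(tols, function(tl) {
        d <- find_dominant_regions(rd, "hypo", tol = tl)
        expect_true(any(d$is_extreme))
        expect_equal(d$delta_beta[d$is_extreme], min(rd$delta_beta))
        d$region
      })
      expect_true(all(sets[[1]] %in% sets[[2]]))
      expect_true(all(sets[[2]] %in% sets[[3]]))
    }
  })
})

test_that("per-region DMG status flags regions beyond the pooled thresholds", {
  rd <- tibble::tibble(gene = c("GA", "GA", "GB"),
                       region = c("Body", "TSS200", "Body"),
                       delta_beta = c(-0.05, 0.001, 0.07))
  rc <- region_dmg_calls(rd, thresholds = c(-0.01, 0.02))
  expect_equal(rc$call[rc$gene == "GA"], "hypo")
  expect_equal(rc$call[rc$gene == "GB"], "hyper")
  expect_equal(nrow(rc), 2)
})
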