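test_that("dropout rates are zero-count proportions per fraction", {
  x <- rbind(A = c(0, 0, 0, 0, 1, 2, 3, 1, 2, 1),
             B = rep(1, 10),
             C = rep(0, 10))
  colnames(x) <- sprintf("c%d", 1:10)
  mask <- rep(c(TRUE, FALSE), each = 5)
  d <- dropout_rates(x, mask)
  expect_equal(d$d_T[d$gene == "A"], 0.8)
  expect_equal(d$d_N[d$gene == "A"], 0.0)
  expect_equal(d$d_T[d$gene == "B"], 0.0)
  expect_equal(d$d_T[d$gene == "C"], 1.0)
  expect_equal(d$d_N[d$gene == "C"], 1.0)
  expect_error(dropout_rates(x, rep(TRUE, 10)), "non-empty")
})

test_that("dropout quadrants follow the threshold rules and partition", {
  expect_identical(classify_dropout(0.5, 0.9), "tumor_specific")
  expect_identical(classify_dropout(0.9, 0.5), "normal_specific")
  expect_identical(classify_dropout(0.5, 0.5), "common_positive")
  expect_identical(classify_dropout(0.9, 0.9), "common_negative")
  expect_identical(classify_dropout(0.75, 0.75), "common_negative")
  expect_identical(classify_dropout(0.74999, 0.75), "tumor_specific")
  expect_error(classify_dropout(0.5, 0.5, tau = 1.5), "tau")
  expect_error(classify_dropout(1.2, 0.5), "\\[0, 1\\]")

  # partition property: exactly one category for any rate pair and tau
  set.seed(31)
  for (tau in c(0.25, 0.5, 0.75, 0.9)) {
    d_T <- runif(200); d_N <- runif(200)
    cats <- classify_dropout(d_T, d_N, tau)
    expect_true(all(cats %in% c("tumor_specific", "normal_specific",
                                "common_negative", "common_positive")))
    expect_identical(classify_dropout(d_T, d_N, tau), cats)
    # category boundaries re-derived independently
    manual <- ifelse(d_T < tau & d_N >= tau, "tumor_specific",
              ifelse(d_T >= tau & d_N < tau, "normal_specific",
              ifelse(d_T < tau, "common_positive", "common_negative")))
    expect_identical(cats, manual)
  }
})

test_that("cluster overrides move whole clusters between fractions", {
  clusters <- rep(c(1L, 2L, 3L), each = 4)
  kp <- c("1" = TRUE, "2" = TRUE, "3" = FALSE)
  base <- tumor_mask(clusters, kp)
  expect_identical(sum(base), 8L)
  # a keratin-positive cluster annotated as normal epithelium is reassigned
  # to the non-tumor fraction for screening
  over <- tumor_mask(clusters, kp, override = c("2" = FALSE))
  expect_identical(sum(over), 4L)
  expect_true(all(over[clusters == 1L]))
  expect_false(any(over[clusters == 2L]))
  expect_error(tumor_mask(clusters, kp, override = c("9" = TRUE)), "unknown")
})

test_that("top ranking uses total tumor expression with alphabetical ties", {
  prof <- data.frame(gene = c("B", "A", "C", "D"),
                     d_T = 0.1, d_N = 0.9,
                     category = c("tumor_specific", "tumor_specific",
                                  "common_positive", "tumor_specific"),
                     total_tumor_expression = c(10, 10, 8, 1))
  top <- top_tumor_specific(prof, K = 3)
  expect_identical(top$gene, c("A", "B", "C"))
  expect_identical(top$rank, 1:3)
  strict <- top_tumor_specific(prof, K = 3, strict = TRUE)
  expect_identical(strict$gene, c("A", "B", "D"))
  expect_error(top_tumor_specific(prof, K = 0), "K")
})

test_that("cluster z-scores are row-standardized with population SD", {
  x <- rbind(g1 = c(0, 0, 2, 2), g2 = c(1, 1, 1, 1), g3 = c(0, 2, 4, 6))
  colnames(x) <- sprintf("c%d", 1:4)
  cl <- c(1L, 1L, 2L, 2L)
  z <- cluster_zscore_matrix(x, cl)
  expect_equal(unname(z["g1", ]), c(-1, 1))          # means 0,2 -> +-1 pop SD
  expect_equal(unname(z["g2", ]), c(0, 0))           # flat gene -> all zero
  expect_identical(attr(z, "sd_convention"), "population")
  # row identity: mean 0, population SD 1 for non-degenerate rows
  run <- default_spatial_run()
  z2 <- cluster_zscore_matrix(run$norm_post, run$clusters_post,
                              c("SLC2A1", "EPCAM", "KRT7"))
  expect_equal(unname(rowMeans(z2)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 1, function(r) sqrt(mean((r - mean(r))^2)))),
               rep(1, 3), tolerance = 1e-12)
  expect_error(cluster_zscore_matrix(x, rep(1L, 4)), "at least 2")
})

test_that("z-scores peak in tumor-enriched clusters for planted markers", {
  run <- default_spatial_run()
  z <- cluster_zscore_matrix(run$norm_post, run$clusters_post,
                             c("SLC2A1", "TS20", "NS20"))
  kp_ids <- names(run$kp)[run$kp]
  kp_ids <- intersect(kp_ids, colnames(z))
  kn_ids <- setdiff(colnames(z), kp_ids)
  expect_gt(max(z["SLC2A1", kp_ids]), max(z["SLC2A1", kn_ids]))
  expect_gt(max(z["TS20", kp_ids]), max(z["TS20", kn_ids]))
  expect_gt(max(z["NS20", kn_ids]), max(z["NS20", kp_ids]))
})

test_that("sample intersection is sorted, commutative and idempotent", {
  expect_identical(intersect_samples(c("A", "B", "C"), c("C", "B", "D")),
                   c("B", "C"))
  expect_identical(intersect_samples(c("A"), c("B")), character(0))
  expect_identical(intersect_samples(c("B", "A"), c("A", "B")), c("A", "B"))
  expect_identical(intersect_samples(c("A", "B"), c("B", "A")),
                   intersect_samples(c("B", "A"), c("A", "B")))
  shared <- intersect_samples(c("A", "B"), c("B", "C"))
  expect_identical(intersect_samples(shared, shared), shared)
})

test_that("subtype annotation uses containing tumor regions only", {
  run <- default_spatial_run()
  sub <- annotate_subtypes(run$post$cells, run$sim$regions)
  truth <- run$sim$truth$label[run$post$cells$cell_id]
  labeled <- !is.na(sub)
  expect_true(all(sub[labeled] == truth[labeled]))
  expect_true(all(is.na(sub[truth == "non_tumor"])))
  expect_identical(sum(table(sub)), sum(labeled))

  rect <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  bad <- list(list(region_id = "a", label = "ADC",
                   polygon = rect(0, 0, 10, 10)),
              list(region_id = "b", label = "SCC",
                   polygon = rect(5, 5, 15, 15)))
  expect_error(annotate_subtypes(run$post$cells[1:5, ], bad),
               "overlapping tumor regions")
})

test_that("subtype positivity reports fractions, means and deltas", {
  x <- rbind(G1 = c(1, 1, 0, 0, 0, 0), G2 = c(1, 1, 1, 1, 1, 1))
  colnames(x) <- sprintf("c%d", 1:6)
  sub <- c("ADC", "ADC", "TTF1neg_p40neg", "TTF1neg_p40neg", "SCC", "SCC")
  names(sub) <- colnames(x)
  sp <- subtype_positivity(x, x, sub, c("G1", "G2"))
  g1 <- sp[sp$gene == "G1", ]
  expect_equal(g1$frac_ADC, 1)
  expect_equal(g1$frac_SCC, 0)
  expect_equal(g1$delta_ADC_TTF1neg, 1)
  g2 <- sp[sp$gene == "G2", ]
  expect_equal(g2$delta_ADC_TTF1neg, 0)
  expect_equal(g2$delta_TTF1neg_SCC, 0)
  # sorted by descending ADC positivity
  expect_true(all(diff(sp$frac_ADC) <= 0))
  expect_error(subtype_positivity(x, x, sub[1:4], c("G1")), "SCC")
})

test_that("planted SLC2A1-like monotone subtype gradient is recovered", {
  run <- default_spatial_run()
  mask <- tumor_mask(run$clusters_post, run$kp)
  sub <- annotate_subtypes(run$post$cells, run$sim$regions)
  sub[!mask] <- NA
  sp <- subtype_positivity(run$post$counts, run$norm_post, sub, "SLC2A1")
  expect_gt(sp$frac_SCC, sp$frac_TTF1neg_p40neg)
  expect_gt(sp$frac_TTF1neg_p40neg, sp$frac_ADC)
})
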