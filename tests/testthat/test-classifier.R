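# Marker-panel construction and nearest-centroid stage calling.

make_de_table <- function(n_down, n_up, n_ns = 50) {
  tibble::tibble(
    transcript_id = sprintf("g%04d", seq_len(n_down + n_up + n_ns)),
    base_mean = 100,
    lfc = c(rep(-2, n_down), rep(1.5, n_up), rep(0.1, n_ns)),
    padj = c(seq(1e-10, 1e-3, length.out = n_down + n_up), rep(0.9, n_ns)),
    p_value = 1e-4, direction = c(rep(-1, n_down), rep(1, n_up), rep(1, n_ns)))
}

test_that("panel takes exactly n_down + n_up markers by adjusted p-value", {
  de <- make_de_table(300, 150)
  model <- build_classifier(de, de$transcript_id)
  expect_s3_class(model, "nsn_sn_classifier")
  expect_equal(nrow(model$markers), 100L)
  expect_equal(sum(model$markers$direction == "down_in_SN"), 65L)
  expect_equal(sum(model$markers$direction == "up_in_SN"), 35L)

  tiny <- build_classifier(make_de_table(1, 1), make_de_table(1, 1)$transcript_id,
                           n_down = 1, n_up = 1)
  expect_equal(nrow(tiny$markers), 2L)
})

test_that("panel construction is invariant to DE-table row order", {
  de <- make_de_table(100, 60)
  m1 <- build_classifier(de, de$transcript_id)
  m2 <- build_classifier(de[withr::with_seed(1, sample(nrow(de))), ],
                         de$transcript_id)
  expect_identical(m1$markers, m2$markers)
})

test_that("insufficient candidates error with available counts", {
  de <- make_de_table(64, 40)
  expect_error(build_classifier(de, de$transcript_id), "64 down-regulated")
})

test_that("reference projection reproduces stored centroids", {
  sim <- simulate_counts(sim_config(seed = 61, n_transcripts = 1000))
  de <- suppressMessages(differential_expression(sim$counts, sim$meta))
  model <- build_classifier(de, c(sim$truth$degraded_ids, sim$truth$up_ids),
                            n_down = 30, n_up = 12)
  model <- fit_reference(model, sim$counts, sim$meta)
  calls <- classify_stage(model, sim$counts, sim$meta)
  # re-projected reference centroids match the stored ones to 1e-9
  sc <- as.matrix(calls[, paste0("PC", seq_len(model$k))])
  for (st in c("NSN", "SN")) {
    expect_equal(colMeans(sc[calls$stage == st, , drop = FALSE]),
                 model$centroids[st, ], tolerance = 1e-9)
  }
  # a query identical to a reference sample gets that sample's stage
  expect_equal(calls$call, unname(sim$truth$stage[calls$sample_id]))
  expect_true(all(calls$confidence_ratio[calls$call != "unclassified"] <= 0.8))
})

test_that("leave-one-out self-classification is perfect at the default effect", {
  sim <- simulate_counts(sim_config(seed = 62, n_transcripts = 800))
  de <- suppressMessages(differential_expression(sim$counts, sim$meta))
  model0 <- build_classifier(de, c(sim$truth$degraded_ids, sim$truth$up_ids),
                             n_down = 30, n_up = 12)
  hits <- 0; total <- 0
  for (i in seq_len(nrow(sim$meta))) {
    keep <- sim$meta$sample_id[-i]
    held <- sim$meta$sample_id[i]
    m <- fit_reference(model0,
                       sim$counts[, c("transcript_id", keep)],
                       sim$meta[-i, ])
    cl <- classify_stage(m, sim$counts[, c("transcript_id", held)])
    total <- total + 1
    if (cl$call == sim$meta$stage[i]) hits <- hits + 1
  }
  expect_equal(hits, total)
})

test_that("a query at the exact centroid midpoint is unclassified", {
  model <- structure(list(
    markers = tibble::tibble(transcript_id = c("g1", "g2"),
                             direction = c("down_in_SN", "up_in_SN"),
                             padj = 1e-6, lfc = c(-2, 2)),
    marker_mean = c(g1 = 2, g2 = 3), marker_sd = c(g1 = 1, g2 = 1),
    rotation = diag(2), centroids = rbind(NSN = c(-1, 0), SN = c(1, 0)),
    k = 2, fitted = TRUE), class = "nsn_sn_classifier")
  colnames(model$rotation) <- c("PC1", "PC2")
  rownames(model$rotation) <- c("g1", "g2")
  # counts (3, 7): lognorm = (2, 3) = stored means -> z = (0,0) = midpoint
  q <- make_counts(cbind(s1 = c(3, 7)), ids = c("g1", "g2"))
  cl <- classify_stage(model, q)
  expect_equal(cl$call, "unclassified")
  expect_equal(cl$confidence_ratio, 1)
})

test_that("duplicated query samples get identical projections", {
  sim <- simulate_counts(sim_config(seed = 63, n_transcripts = 600))
  de <- suppressMessages(differential_expression(sim$counts, sim$meta))
  model <- build_classifier(de, c(sim$truth$degraded_ids, sim$truth$up_ids),
                            n_down = 20, n_up = 8)
  model <- fit_reference(model, sim$counts, sim$meta)
  q <- sim$counts[, c("transcript_id", "NSN_01", "NSN_02")]
  q$NSN_02 <- q$NSN_01
  names(q) <- c("transcript_id", "a", "b")
  cl <- classify_stage(model, q)
  expect_equal(cl$PC1[1], cl$PC1[2])
  expect_equal(cl$dist_nsn[1], cl$dist_nsn[2])
})

test_that("low marker coverage errors; moderate gaps are imputed", {
  sim <- simulate_counts(sim_config(seed = 64, n_transcripts = 600))
  de <- suppressMessages(differential_expression(sim$counts, sim$meta))
  model <- build_classifier(de, c(sim$truth$degraded_ids, sim$truth$up_ids),
                            n_down = 20, n_up = 10)
  model <- fit_reference(model, sim$counts, sim$meta)
  ids <- model$markers$transcript_id
  # drop 10% of markers -> imputation notice, still classifies
  q_ok <- sim$counts[!sim$counts$transcript_id %in% ids[1:3], ]
  expect_message(cl <- classify_stage(model, q_ok), "imputing")
  expect_equal(nrow(cl), nrow(sim$meta))
  # drop 30% of markers -> error
  q_bad <- sim$counts[!sim$counts$transcript_id %in% ids[1:9], ]
  expect_error(classify_stage(model, q_bad), "80%")
})

test_that("cohort skew report matches the hypergeometric Fisher test", {
  calls <- tibble::tibble(
    call = c(rep("NSN", 10), rep("SN", 10)),
    condition = c(rep("KO", 10), rep("WT", 10)))
  rep_out <- cohort_skew_report(calls)
  # oracle: two-sided Fisher by hypergeometric enumeration on [[10,0],[0,10]]
  probs <- dhyper(0:10, 10, 10, 10)
  p_obs <- dhyper(10, 10, 10, 10)
  p_oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  expect_equal(rep_out$test$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(rep_out$test$p_value, 1.082e-5, tolerance = 1e-3)

  bal <- tibble::tibble(call = rep(c("NSN", "SN"), 10),
                        condition = rep(c("KO", "WT"), each = 10))
  expect_equal(cohort_skew_report(bal)$test$p_value, 1)
})

test_that("skewed synthetic cohorts are flagged by the report", {
  ref <- simulate_counts(sim_config(seed = 70, n_transcripts = 800))
  de <- suppressMessages(differential_expression(ref$counts, ref$meta))
  model <- build_classifier(de, c(ref$truth$degraded_ids, ref$truth$up_ids),
                            n_down = 25, n_up = 10)
  model <- fit_reference(model, ref$counts, ref$meta)
  wt <- simulate_counts(sim_config(seed = 71, transcriptome_seed = 70,
                                   n_transcripts = 800, n_nsn = 1, n_sn = 12))
  ko <- simulate_counts(sim_config(seed = 72, transcriptome_seed = 70,
                                   n_transcripts = 800, n_nsn = 8, n_sn = 5))
  calls <- dplyr::bind_rows(
    dplyr::mutate(classify_stage(model, wt$counts), condition = "WT"),
    dplyr::mutate(classify_stage(model, ko$counts), condition = "KO"))
  rep_out <- cohort_skew_report(calls)
  expect_lt(rep_out$test$p_value, 0.05)
})

test_that("tidy and glance summarise the classifier", {
  de <- make_de_table(80, 40)
  model <- build_classifier(de, de$transcript_id, n_down = 10, n_up = 5)
  expect_equal(nrow(tidy(model)), 15)
  g <- glance(model)
  expect_equal(g$n_down, 10)
  expect_false(g$fitted)
})
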