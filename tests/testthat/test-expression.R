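# Transcriptome-complexity statistics and filters.

test_that("detected_transcripts counts threshold crossings", {
  m <- cbind(s1 = c(0, 1, 5), s2 = c(0, 0, 0), s3 = c(2, 2, 2))
  det <- detected_transcripts(make_counts(m))
  expect_equal(det$detected[det$sample_id == "s1"], 2L)
  expect_equal(det$detected[det$sample_id == "s2"], 0L)
  expect_equal(det$detected[det$sample_id == "s3"], 3L)
  det5 <- detected_transcripts(make_counts(m), min_count = 5)
  expect_equal(det5$detected, c(1L, 0L, 0L))
})

test_that("depth-matched Wilcoxon matches exact enumeration", {
  det <- tibble::tibble(
    sample_id = letters[1:6],
    stage = rep(c("NSN", "SN"), each = 3),
    total_reads = rep(1e6, 6),
    detected = c(100L, 101L, 102L, 1L, 2L, 3L))
  res <- depth_matched_comparison(det, band = c(0, 2e6))
  # enumeration oracle: all 20 assignments of 3-of-6 ranks to NSN
  vals <- det$detected
  combos <- utils::combn(6, 3)
  rk <- rank(vals)
  obs_w <- sum(rk[1:3]) - 3 * 4 / 2
  ws <- apply(combos, 2, function(idx) sum(rk[idx]) - 3 * 4 / 2)
  p_exact <- mean(ws >= obs_w) + mean(ws <= (9 - obs_w))
  expect_equal(res$p_value, p_exact, tolerance = 1e-9)
  expect_equal(res$p_value, 0.1, tolerance = 1e-9)

  # identical groups -> p near 1
  det2 <- det
  det2$detected <- rep(c(5L, 6L, 7L), 2)
  res2 <- depth_matched_comparison(det2, band = c(0, 2e6))
  expect_gte(res2$p_value, 0.9)

  # banding that empties a group errors
  det3 <- det
  det3$total_reads <- c(1e6, 1e6, 1e6, 9e6, 9e6, 9e6)
  expect_error(depth_matched_comparison(det3, band = c(0, 2e6)), "empty")
})

test_that("SN-missing filter applies both criteria at exact thresholds", {
  n_nsn <- 9; n_sn <- 16
  meta <- make_meta(c(sprintf("N%02d", 1:n_nsn), sprintf("S%02d", 1:n_sn)),
                    c(rep("NSN", n_nsn), rep("SN", n_sn)))
  base <- matrix(5, nrow = 4, ncol = n_nsn + n_sn,
                 dimnames = list(NULL, meta$sample_id))
  # tx1: 7 NSN present, 10 SN zero  -> selected (boundary)
  base[1, ] <- c(rep(1, 7), 0, 0, rep(0, 10), rep(1, 6))
  # tx2: only 6 NSN present        -> rejected
  base[2, ] <- c(rep(1, 6), 0, 0, 0, rep(0, 16))
  # tx3: all zero                  -> rejected (criterion 1)
  base[3, ] <- 0
  # tx4: present everywhere        -> rejected (criterion 2)
  sel <- sn_missing_filter(make_counts(base), meta)
  expect_equal(sel$transcript_id, "tx001")
})

test_that("raising sn_zero_frac never adds transcripts (monotone)", {
  set.seed(1)
  m <- matrix(rbinom(50 * 25, 3, 0.3), nrow = 50)
  colnames(m) <- c(sprintf("N%d", 1:9), sprintf("S%d", 1:16))
  meta <- make_meta(colnames(m), c(rep("NSN", 9), rep("SN", 16)))
  counts <- make_counts(m)
  prev <- sn_missing_filter(counts, meta, sn_zero_frac = 0.2)$transcript_id
  for (f in c(0.4, 0.6, 0.8, 1.0)) {
    cur <- sn_missing_filter(counts, meta, sn_zero_frac = f)$transcript_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("quartiles partition expressed transcripts with near-equal sizes", {
  m <- cbind(a = c(4, 3, 2, 1), b = c(4, 3, 2, 1))
  meta <- make_meta(c("a", "b"), c("NSN", "NSN"))
  q <- expression_quartiles(make_counts(m), meta)
  expect_equal(as.character(q$quartile), c("Q4", "Q3", "Q2", "Q1"))

  # ties broken by transcript id order, 2 per quartile
  m2 <- cbind(a = rep(c(2, 2, 4, 4, 6, 6, 8, 8), 1))
  meta2 <- make_meta("a", "NSN")
  q2 <- expression_quartiles(make_counts(m2), meta2)
  expect_equal(as.integer(table(q2$quartile)), rep(2L, 4))
  expect_equal(as.character(q2$quartile[1:2]), c("Q1", "Q1"))

  # larger matrix: sizes within 1 of n/4
  sim <- simulate_counts(sim_config(seed = 2, n_transcripts = 1000))
  q3 <- expression_quartiles(sim$counts, sim$meta)
  sizes <- as.integer(table(q3$quartile))
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_equal(sum(sizes), nrow(q3))
})

test_that("quartile bias chi-square equals the hand-computed statistic", {
  quartiles <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:100),
    quartile = factor(rep(paste0("Q", 1:4), each = 25),
                      levels = paste0("Q", 1:4)))
  # observed (40,30,20,10) against uniform expectation of 25 each
  # (duplicated selections are counted, so 40 can exceed the 25 Q1 ids)
  selected <- c(sprintf("t%03d", 1:25), sprintf("t%03d", 1:15),
                sprintf("t%03d", 26:50), sprintf("t%03d", 26:30),
                sprintf("t%03d", 51:70), sprintf("t%03d", 76:85))
  res <- quartile_bias_test(selected, quartiles)
  obs <- c(res$Q1, res$Q2, res$Q3, res$Q4)
  expect_equal(obs, c(40L, 30L, 20L, 10L))
  oracle <- sum((obs - 25)^2 / 25)
  expect_equal(res$statistic, oracle, tolerance = 1e-9)
  expect_equal(res$statistic, 20, tolerance = 1e-9)
  expect_equal(res$df, 3)

  # uniform selection -> statistic 0, p = 1
  res0 <- quartile_bias_test(sprintf("t%03d", seq(1, 100)), quartiles)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
})

test_that("SN-missing transcripts are biased to low NSN expression quartiles", {
  sim <- simulate_counts(sim_config(seed = 23, n_transcripts = 3000,
                                    frac_missing = 0.05))
  q <- expression_quartiles(sim$counts, sim$meta, group = "NSN")
  res <- quartile_bias_test(sim$truth$missing_ids, q)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$Q1 + res$Q2, res$Q3 + res$Q4)
})

test_that("over-dispersion flags control type I error and detect inflation", {
  n <- 16
  null_frac <- power_hits <- numeric(20)
  for (r in 1:20) {
    set.seed(100 + r)
    mu <- rep(c(20, 50, 100, 200), each = 75)
    m <- matrix(rpois(300 * 2 * n, rep(mu, 2 * n)), nrow = 300)
    # plant one transcript with ~10x inflated variance in both groups
    m[1, ] <- rnbinom(2 * n, mu = 100, size = 100 / 9)
    colnames(m) <- c(sprintf("N%d", 1:n), sprintf("S%d", 1:n))
    meta <- make_meta(colnames(m), rep(c("NSN", "SN"), each = n))
    od <- overdispersion_compare(make_counts(m), meta)
    null_frac[r] <- mean(od$overdispersed[od$transcript_id != "tx001"])
    power_hits[r] <- any(od$overdispersed[od$transcript_id == "tx001"])
  }
  expect_lte(mean(null_frac), 0.07)
  expect_gte(sum(power_hits), 18)
})

test_that("over-dispersion counts are symmetric for identical groups", {
  set.seed(77)
  mu <- rexp(400, 1 / 80)
  m <- matrix(rnbinom(400 * 24, mu = rep(mu, 24), size = 5), nrow = 400)
  colnames(m) <- sprintf("c%02d", 1:24)
  meta <- make_meta(colnames(m), rep(c("NSN", "SN"), each = 12))
  od <- overdispersion_compare(make_counts(m), meta)
  n_nsn <- sum(od$overdispersed[od$group == "NSN"])
  n_sn <- sum(od$overdispersed[od$group == "SN"])
  if (n_nsn + n_sn > 0) {
    expect_gt(binom.test(n_nsn, n_nsn + n_sn, 0.5)$p.value, 0.01)
  } else {
    succeed("no flags in either group")
  }
})
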