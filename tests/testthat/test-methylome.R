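# QC, global methylation, segmentation, pseudobulk machinery.

test_that("QC thresholds are strict and verdicts itemized", {
  calls_ok <- make_calls("chr1", c(10, 20, 30, 40), c(1, 1, 0, 1), c(0, 0, 1, 0))
  noncpg <- make_calls("chr1", c(100, 110), c(0, 0), c(1, 1), context = "non-CpG")
  noncpg$meth <- c(4, 0); noncpg$unmeth <- c(96, 100)   # 2% non-CpG level
  cells <- dplyr::bind_rows(
    make_cell("pass", "NSN", dplyr::bind_rows(calls_ok, noncpg),
              mapping = 50, n_cpg = 500001),
    make_cell("low_map", "NSN", dplyr::bind_rows(calls_ok, noncpg),
              mapping = 9.9, n_cpg = 600000),
    make_cell("boundary_map", "NSN", dplyr::bind_rows(calls_ok, noncpg),
              mapping = 10, n_cpg = 600000),
    make_cell("low_cov", "NSN", dplyr::bind_rows(calls_ok, noncpg),
              mapping = 50, n_cpg = 500000))
  res <- qc_filter(cells)
  expect_setequal(res$cells$cell_id, "pass")
  rep <- res$report
  expect_false(rep$pass_mapping[rep$cell_id == "low_map"])
  expect_false(rep$pass_mapping[rep$cell_id == "boundary_map"])  # strict >
  expect_false(rep$pass_cpgs[rep$cell_id == "low_cov"])          # strict >
})

test_that("planted contaminated cells are exactly the ones flagged", {
  cfg <- quick_meth_cfg(seed = 41, n_contaminated = 2)
  sm <- simulate_methylomes(cfg)
  res <- qc_filter(sm$cells, min_cpgs = 1000)
  flagged <- res$report$cell_id[res$report$contaminated]
  expect_setequal(flagged, sm$truth$contaminated_ids)
})

test_that("global methylation is the pooled call ratio", {
  cc <- make_calls("chr1", 1:4, c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(global_methylation(cc)$global_pct, 50)
  cc2 <- make_calls("chr1", 1:3, c(1, 1, 1), c(0, 0, 0))
  expect_equal(global_methylation(cc2)$global_pct, 100)
  # no calls in context -> NA
  expect_true(is.na(global_methylation(cc, context = "non-CpG")$global_pct))
})

test_that("global methylation equals a line-by-line file oracle", {
  cfg <- sim_config(seed = 44, n_nsn = 1, n_sn = 1,
                    genome_spec = tibble::tibble(chrom = "chrA", length = 2e6))
  sm <- simulate_methylomes(cfg)
  cc <- sm$cells$calls[[1]]
  path <- withr::local_tempfile(fileext = ".cov")
  write_bismark_cov(cc, path)
  lines <- strsplit(readLines(path), "\t")
  ctx <- vapply(lines, `[`, character(1), 7)
  meth <- as.numeric(vapply(lines, `[`, character(1), 5))
  unmeth <- as.numeric(vapply(lines, `[`, character(1), 6))
  oracle <- 100 * sum(meth[ctx == "CpG"]) /
    sum(meth[ctx == "CpG"] + unmeth[ctx == "CpG"])
  expect_equal(global_methylation(cc)$global_pct, oracle, tolerance = 1e-9)
})

test_that("synthetic global methylation tracks the truth-implied value", {
  cfg <- quick_meth_cfg(seed = 46)
  sm <- simulate_methylomes(cfg)
  # truth: CpG-weighted mean of domain methylation per stage
  idx <- oostage:::site_domain_index(sm$truth$cpg_positions, sm$domains)
  truth_sn <- mean(sm$domains$true_meth_sn[idx])
  gm <- global_methylation(sm$cells)
  est_sn <- mean(gm$global_pct[sm$cells$stage == "SN"])
  expect_lt(abs(est_sn - truth_sn), 1.5)
})

test_that("segmentation merges runs and partitions the covered genome", {
  track <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, 11) * 1000, end = seq(1, 12) * 1000,
    meth = c(10, 10, 10, 10, 80, 80, 80, 80, 40, 40, 40, 40))
  seg <- segment_domains(track)
  expect_equal(seg$class, c("unmethylated", "methylated", "intermediate"))
  expect_equal(seg$start, c(0, 4000, 8000))
  expect_equal(seg$end, c(4000, 8000, 12000))
  # partition: total length preserved
  expect_equal(sum(seg$end - seg$start), sum(track$end - track$start))

  # uniform track -> one domain per chromosome
  t2 <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 5),
                       start = rep(0:4 * 1000, 2), end = rep(1:5 * 1000, 2),
                       meth = 10)
  seg2 <- segment_domains(t2)
  expect_equal(nrow(seg2), 2)
  expect_equal(unique(seg2$class), "unmethylated")

  # idempotent: re-segmenting the segmented track changes nothing
  reseg <- segment_domains(
    tibble::tibble(chrom = seg$chrom, start = seg$start, end = seg$end,
                   meth = c(10, 80, 40)))
  expect_equal(reseg[, c("chrom", "start", "end", "class")],
               seg[, c("chrom", "start", "end", "class")])

  expect_error(segment_domains(track, low = 70, high = 25), "low")
})

test_that("segmentation recovers the generator's domain classes", {
  cfg <- sim_config(seed = 47, n_nsn = 2, n_sn = 2,
                    genome_spec = tibble::tibble(chrom = "chrA", length = 8e6))
  sm <- simulate_methylomes(cfg, mode = "expectation")
  track <- tile_genome(cfg$genome_spec, 2000)
  idx <- oostage:::midpoint_containment(track, sm$domains)
  track$meth <- sm$domains$true_meth_nsn[idx]
  seg <- segment_domains(track)
  expect_equal(nrow(seg), nrow(sm$domains))
  expect_equal(seg$class, sm$domains$class)
  expect_equal(seg$start, sm$domains$start)
  expect_equal(seg$end, sm$domains$end)
})

test_that("pseudobulk groups are disjoint, exhaustive per draw and seeded", {
  cells <- tibble::tibble(cell_id = sprintf("c%02d", 1:12), stage = "NSN",
                          calls = list(NULL))
  g1 <- pseudobulk_groups(cells, seed = 5)
  expect_equal(nrow(g1), 12)
  expect_equal(anyDuplicated(g1$cell_id), 0L)
  expect_equal(as.integer(table(g1$group)), c(4L, 4L, 4L))
  g2 <- pseudobulk_groups(cells, seed = 5)
  expect_identical(g1, g2)
  expect_error(pseudobulk_groups(cells[1:11, ]), "12")
})

test_that("100 iterations over 28 cells give mostly distinct partitions", {
  cells <- tibble::tibble(cell_id = sprintf("c%02d", 1:28), stage = "SN",
                          calls = list(NULL))
  sigs <- vapply(1:100, function(i) {
    g <- pseudobulk_groups(cells, seed = oostage:::sub_seed(99, i))
    paste(vapply(split(sort(g$cell_id), g$group[order(g$cell_id)]),
                 paste, character(1), collapse = ","), collapse = ";")
  }, character(1))
  expect_gte(length(unique(sigs)), 95)
})

test_that("domain methylation pools counts across member cells", {
  domains <- tibble::tibble(chrom = "chr1", start = 0, end = 1000,
                            class = "intermediate", domain_id = "d1")
  c1 <- make_calls("chr1", c(10, 20, 30, 40), c(1, 1, 1, 0), c(0, 0, 0, 1))
  c2 <- make_calls("chr1", c(50, 60, 70, 80), c(1, 0, 0, 0), c(0, 1, 1, 1))
  cells <- dplyr::bind_rows(make_cell("a", "NSN", c1), make_cell("b", "NSN", c2))
  dm <- domain_methylation(cells, domains, min_calls = 1)
  expect_equal(dm$pct, 50)
  expect_equal(dm$total, 8)
  # empty domain -> uncovered
  d2 <- tibble::tibble(chrom = "chr2", start = 0, end = 1000,
                       class = "intermediate", domain_id = "d2")
  dm2 <- domain_methylation(cells, d2, min_calls = 1)
  expect_false(dm2$covered)
})
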