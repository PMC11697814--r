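# Small fixtures built in code.

# Wide count tibble from a plain matrix.
make_counts <- function(m, ids = NULL) {
  ids <- ids %||% sprintf("tx%03d", seq_len(nrow(m)))
  dplyr::bind_cols(tibble::tibble(transcript_id = ids),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

make_meta <- function(sample_ids, stages, total_reads = NULL) {
  tibble::tibble(sample_id = sample_ids, stage = stages,
                 source = "fixture",
                 total_reads = total_reads %||% rep(1e6, length(sample_ids)))
}

# Group-level domain methylation rows for dmr_iteration(): per stage,
# `n_groups` groups each holding an equal share of (meth, total).
make_group_counts <- function(domain_id, meth_nsn, total_nsn, meth_sn,
                              total_sn, n_groups = 3) {
  rows <- list()
  for (st in c("NSN", "SN")) {
    meth <- if (st == "NSN") meth_nsn else meth_sn
    tot <- if (st == "NSN") total_nsn else total_sn
    for (g in seq_len(n_groups)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        domain_id = domain_id, stage = st, group = g,
        meth = meth / n_groups, total = tot / n_groups,
        covered = TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

# One cell row in the simulate_methylomes() layout.
make_cell <- function(cell_id, stage, calls, mapping = 50, n_cpg = NULL) {
  tibble::tibble(
    cell_id = cell_id, stage = stage,
    mapping_efficiency = mapping,
    n_cpg = n_cpg %||% sum(calls$context == "CpG"),
    calls = list(calls))
}

make_calls <- function(chrom, pos, meth, unmeth, context = "CpG") {
  tibble::tibble(chrom = chrom, pos = pos, context = context,
                 meth = meth, unmeth = unmeth)
}

# A small sim_config for fast tests.
quick_meth_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_nsn = 12, n_sn = 28,
             genome_spec = tibble::tibble(chrom = c("chrA", "chrB"),
                                          length = c(8e6, 8e6)),
             n_planted_dmrs = 5, ...)
}

`%||%` <- rlang::`%||%`
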