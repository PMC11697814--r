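#' Simulate sparse single-cell methylomes over a domain-structured genome
#'
#' Tiles each chromosome with methylation domains (unmethylated,
#' intermediate, methylated) whose true methylation levels are drawn from
#' the class-defining ranges (0-25%, 25-70%, 70-100%). Planted hyper-DMRs
#' raise the SN-cell methylation of `n_planted_dmrs` intermediate domains
#' by `dmr_effect` percentage points. Each cell observes a Bernoulli
#' subsample of the genome's CpGs at `coverage_frac`; observed CpGs carry
#' single-read (0/1) calls drawn from the domain's true methylation, the
#' realistic single-cell bisulfite regime. Non-CpG sites are emitted at a
#' low density with stage-specific methylation levels. Domain boundaries
#' are aligned to the 2-kb quantification grid.
#'
#' @param cfg A [sim_config()].
#' @param mode `"read"` (default) for 0/1 single-read calls;
#'   `"expectation"` for a deterministic infinite-coverage limit in which
#'   every CpG is observed once with fractional methylated /
#'   unmethylated counts equal to the true domain methylation.
#' @return A list of class `sim_meth` with elements `cells` (tibble: one
#'   row per cell with `cell_id`, `stage`, `mapping_efficiency`, `n_cpg`
#'   and a `calls` list-column of call tibbles `chrom`, `pos` (0-based),
#'   `context`, `meth`, `unmeth`), `domains` (tibble of intervals with
#'   class and true per-stage methylation) and `truth` (planted DMR table,
#'   contaminated cell ids, CpG positions).
#' @export
simulate_methylomes <- function(cfg, mode = c("read", "expectation")) {
  validate_sim_config(cfg)
  mode <- match.arg(mode)
  if (cfg$coverage_frac <= 0 && mode == "read") {
    stop_cfg("coverage_frac", "must be > 0 in read mode")
  }
  if (nrow(cfg$genome_spec) == 0) stop_cfg("genome_spec", "must be nonempty")

  with_seed(sub_seed(cfg$seed, 2L), {
    domains <- draw_domains(cfg)
    # Plant hyper-DMRs preferentially inside intermediate domains with
    # headroom for the full effect.
    inter <- which(domains$class == "intermediate" &
                     domains$true_meth_nsn + cfg$dmr_effect <= 100)
    n_plant <- min(cfg$n_planted_dmrs, length(inter))
    planted_idx <- if (n_plant > 0) sort(sample(inter, n_plant)) else integer(0)
    domains$planted <- FALSE
    domains$planted[planted_idx] <- TRUE
    domains$true_meth_sn <- domains$true_meth_nsn
    domains$true_meth_sn[planted_idx] <-
      domains$true_meth_nsn[planted_idx] + cfg$dmr_effect

    # Genome CpG positions, fixed across cells; sites stay inside the
    # grid-aligned domain territory.
    gs <- cfg$genome_spec
    gs$length <- floor(gs$length / cfg$window_size) * cfg$window_size
    cpg <- draw_sites(gs, cfg$cpg_density)
    cpg$domain <- site_domain_index(cpg, domains)
    noncpg <- draw_sites(gs, cfg$noncpg_density)

    n_cells <- cfg$n_nsn + cfg$n_sn
    stage <- c(rep("NSN", cfg$n_nsn), rep("SN", cfg$n_sn))
    cell_id <- c(sprintf("nsn_cell_%02d", seq_len(cfg$n_nsn)),
                 sprintf("sn_cell_%02d", seq_len(cfg$n_sn)))
    contaminated <- if (cfg$n_contaminated > 0) {
      sample(cell_id, min(cfg$n_contaminated, n_cells))
    } else character(0)

    p_dom <- cbind(NSN = domains$true_meth_nsn, SN = domains$true_meth_sn) / 100

    calls <- vector("list", n_cells)
    n_cpg_cov <- integer(n_cells)
    for (j in seq_len(n_cells)) {
      p_site <- p_dom[cpg$domain, stage[j]]
      if (mode == "expectation") {
        cpg_calls <- tibble(chrom = cpg$chrom, pos = cpg$pos,
                            context = "CpG",
                            meth = p_site, unmeth = 1 - p_site)
      } else {
        obs <- which(runif(nrow(cpg)) < cfg$coverage_frac)
        m <- rbinom(length(obs), 1L, p_site[obs])
        cpg_calls <- tibble(chrom = cpg$chrom[obs], pos = cpg$pos[obs],
                            context = "CpG",
                            meth = as.numeric(m), unmeth = as.numeric(1L - m))
      }
      level <- if (cell_id[j] %in% contaminated) {
        cfg$contaminated_noncpg_level
      } else {
        cfg$noncpg_level[[stage[j]]]
      }
      if (mode == "expectation") {
        nc_calls <- tibble(chrom = noncpg$chrom, pos = noncpg$pos,
                           context = "non-CpG",
                           meth = level / 100, unmeth = 1 - level / 100)
      } else {
        obs <- which(runif(nrow(noncpg)) < cfg$coverage_frac)
        m <- rbinom(length(obs), 1L, level / 100)
        nc_calls <- tibble(chrom = noncpg$chrom[obs], pos = noncpg$pos[obs],
                           context = "non-CpG",
                           meth = as.numeric(m), unmeth = as.numeric(1L - m))
      }
      cc <- bind_rows(cpg_calls, nc_calls)
      cc <- cc[order(cc$chrom, cc$pos), ]
      calls[[j]] <- cc
      n_cpg_cov[j] <- nrow(cpg_calls)
    }

    cells <- tibble(
      cell_id = cell_id, stage = stage,
      mapping_efficiency = runif(n_cells, 25, 60),
      n_cpg = n_cpg_cov,
      calls = calls
    )
    truth <- list(
      planted = domains[domains$planted,
                        c("domain_id", "chrom", "start", "end",
                          "true_meth_nsn", "true_meth_sn")],
      contaminated_ids = contaminated,
      cpg_positions = cpg[, c("chrom", "pos")],
      effect = cfg$dmr_effect
    )
    structure(list(cells = cells, domains = domains, truth = truth),
              class = "sim_meth")
  })
}

# Draw a grid-aligned domain tiling of the genome. Adjacent domains always
# differ in class so the tiling is also the merged segmentation truth.
draw_domains <- function(cfg) {
  dg <- cfg$domain_grammar
  grid <- cfg$window_size
  classes <- names(dg$props)
  out <- list()
  for (i in seq_len(nrow(cfg$genome_spec))) {
    chrom <- cfg$genome_spec$chrom[i]
    len <- floor(cfg$genome_spec$length[i] / grid) * grid
    pos <- 0
    prev <- ""
    cls <- character(0); starts <- numeric(0); ends <- numeric(0)
    while (pos < len) {
      repeat {
        k <- sample(classes, 1L, prob = dg$props)
        if (k != prev) break
      }
      shape <- dg$shape %||% 4
      l <- round(max(stats::rgamma(1, shape = shape,
                                   scale = dg$mean_len[[k]] / shape),
                     dg$min_len) / grid) * grid
      l <- max(l, grid)
      end <- min(pos + l, len)
      cls <- c(cls, k); starts <- c(starts, pos); ends <- c(ends, end)
      pos <- end
      prev <- k
    }
    out[[i]] <- tibble(chrom = chrom, start = starts, end = ends, class = cls)
  }
  domains <- bind_rows(out)
  domains$domain_id <- sprintf("dom%05d", seq_len(nrow(domains)))
  domains$true_meth_nsn <- dplyr::case_when(
    domains$class == "unmethylated" ~ runif(nrow(domains), 0, 25),
    domains$class == "methylated"   ~ runif(nrow(domains), 70, 100),
    TRUE                            ~ runif(nrow(domains), 25, 70)
  )
  domains
}

# Uniform random site positions (0-based) at `density` sites per kb.
draw_sites <- function(genome_spec, density) {
  out <- list()
  for (i in seq_len(nrow(genome_spec))) {
    n <- round(genome_spec$length[i] / 1000 * density)
    if (n < 1) next
    out[[length(out) + 1]] <- tibble(
      chrom = genome_spec$chrom[i],
      pos = sort(sample.int(genome_spec$length[i], n)) - 1L
    )
  }
  bind_rows(out)
}

# Map sites to the tiling domain containing them (domains tile each
# chromosome, so findInterval per chromosome suffices and is fast).
site_domain_index <- function(sites, domains) {
  idx <- integer(nrow(sites))
  for (ch in unique(sites$chrom)) {
    s <- sites$chrom == ch
    d <- which(domains$chrom == ch)
    local_idx <- findInterval(sites$pos[s], domains$start[d])
    local_idx[local_idx < 1] <- NA_integer_
    idx[s] <- d[local_idx]
  }
  idx
}

#' @export
print.sim_meth <- function(x, ...) {
  cat(sprintf("<sim_meth> %d cells, %d domains (%d planted DMRs)\n",
              nrow(x$cells), nrow(x$domains), nrow(x$truth$planted)))
  invisible(x)
}
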