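#' Simulation configuration
#'
#' The generator states a small synthetic world emulating the statistical
#' structure the screen consumes: suggestive GWAS hits in two omics layers
#' plus an LD reference panel with block structure. Planted trios satisfy
#' all three pass conditions (p below threshold, r² > 0.8, within 250 kb)
#' with margin; each distractor violates exactly one named condition, also
#' with margin, so finite-sample LD noise cannot flip outcomes.
#'
#' @param seed RNG seed (integer).
#' @param n_haplotypes number of haplotypes in the panel (2 per diploid
#'   sample; default 200, i.e. 100 samples, a 1000-Genomes-subpopulation
#'   scale).
#' @param planted_trios number of planted pleiotropic loci.
#' @param distractors named integer vector with counts per class:
#'   `below_threshold` (microbe p above its threshold), `low_ld`
#'   (r² far below 0.8), `far_apart` (distance beyond the window).
#' @param allele_freq_range founder allele-frequency interval, bounded away
#'   from 0/1 so LD is defined.
#' @param within_block_r2_target pairwise r² aimed for inside high-LD
#'   blocks (default 0.96; realized values are asserted > 0.9).
#' @param blocks optional explicit block layout: data.frame with columns
#'   chrom, start, n_variants, spacing_bp, r2_target, role. When `NULL`,
#'   [simulate_dataset()] lays out one block per planted/distractor unit.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_haplotypes = 200L, planted_trios = 5L,
                       distractors = c(below_threshold = 10L, low_ld = 10L,
                                       far_apart = 10L),
                       allele_freq_range = c(0.1, 0.9),
                       within_block_r2_target = 0.96,
                       blocks = NULL) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_haplotypes >= 2L, n_haplotypes %% 2L == 0L,
    planted_trios >= 0L,
    all(distractors >= 0L),
    all(c("below_threshold", "low_ld", "far_apart") %in% names(distractors)),
    length(allele_freq_range) == 2L,
    allele_freq_range[1] > 0.05, allele_freq_range[2] < 0.95,
    allele_freq_range[1] <= allele_freq_range[2],
    within_block_r2_target >= 0, within_block_r2_target <= 1
  )
  structure(
    list(seed = as.integer(seed), n_haplotypes = as.integer(n_haplotypes),
         planted_trios = as.integer(planted_trios),
         distractors = distractors,
         allele_freq_range = allele_freq_range,
         within_block_r2_target = within_block_r2_target,
         blocks = blocks),
    class = "sim_config"
  )
}

# default block layout: one block per planted trio / distractor unit, each
# on its own 10 Mb shelf so cross-unit pairs are window-excluded by design.
default_block_layout <- function(cfg) {
  roles <- c(
    rep("planted", cfg$planted_trios),
    rep("below_threshold", cfg$distractors[["below_threshold"]]),
    rep("low_ld", cfg$distractors[["low_ld"]]),
    rep("far_apart", cfg$distractors[["far_apart"]])
  )
  n <- length(roles)
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      n_variants = integer(0), spacing_bp = numeric(0),
                      r2_target = numeric(0), role = character(0),
                      stringsAsFactors = FALSE))
  }
  chrom <- as.character(((seq_len(n) - 1L) %% 22L) + 1L)
  shelf <- ((seq_len(n) - 1L) %/% 22L)
  start <- 1e6 + shelf * 1e7
  spacing <- ifelse(roles == "far_apart", 300000, 50000)
  r2_target <- ifelse(roles == "low_ld", 0, cfg$within_block_r2_target)
  data.frame(chrom = chrom, start = start, n_variants = 2L,
             spacing_bp = spacing, r2_target = r2_target, role = roles,
             stringsAsFactors = FALSE)
}

# one LD block: n_variants binary columns copied from a latent founder with
# per-column flip probability calibrated so pairwise r2 lands near target;
# r2_target = 0 means independent columns. Asserts the margin property.
generate_block <- function(n_hap, n_variants, r2_target, freq_range,
                           max_tries = 50L) {
  draw_poly <- function(p) {
    for (i in seq_len(max_tries)) {
      col <- stats::rbinom(n_hap, 1L, p)
      if (stats::var(col) > 0) return(col)
    }
    stop("could not draw a polymorphic column", call. = FALSE)
  }
  p <- stats::runif(1, freq_range[1], freq_range[2])
  if (r2_target == 0) {
    cols <- replicate(n_variants,
                      draw_poly(stats::runif(1, freq_range[1], freq_range[2])))
    return(cols)
  }
  eps <- (1 - r2_target^(1 / 4)) / 2
  for (attempt in seq_len(max_tries)) {
    founder <- draw_poly(p)
    cols <- vapply(seq_len(n_variants), function(j) {
      for (i in seq_len(max_tries)) {
        flip <- stats::rbinom(n_hap, 1L, eps)
        col <- as.integer(xor(founder, flip))
        if (stats::var(col) > 0) return(col)
      }
      stop("could not draw a polymorphic flipped column", call. = FALSE)
    }, integer(n_hap))
    r2_ok <- TRUE
    if (n_variants >= 2L) {
      for (a in seq_len(n_variants - 1L)) {
        for (b in seq((a + 1L), n_variants)) {
          r2 <- stats::cor(cols[, a], cols[, b])^2
          if (r2_target >= 0.8 && r2 <= 0.9) r2_ok <- FALSE
        }
      }
    }
    if (r2_ok) return(cols)
  }
  stop(sprintf(
    "unreachable r2 target %.3f with %d haplotypes after %d attempts",
    r2_target, n_hap, max_tries), call. = FALSE)
}

#' Simulate a haplotype reference panel with block LD structure
#'
#' Within each block, variants are flipped copies of a latent founder
#' column; the flip probability is calibrated so pairwise r² lands near the
#' block's target (for a per-column flip rate eps, the expected pairwise r²
#' is (1-2 eps)^4). Blocks with target 0 hold mutually independent
#' variants. Across blocks variants are independent, so cross-block r² is
#' finite-sample noise of order 1/n_haplotypes. Realized within-block r²
#' values are recorded in the returned ground truth, and the margin
#' property (high-LD blocks realize r² > 0.9; low-LD blocks < 0.7) is
#' asserted at generation time.
#'
#' @param cfg a [sim_config()]; `cfg$blocks` may give an explicit layout.
#' @return list with `panel` (a [haplotype_panel()]) and `truth` (list with
#'   `blocks` layout incl. variant rsids, and `ld_pairs` with realized r²).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  blocks <- if (is.null(cfg$blocks)) default_block_layout(cfg) else cfg$blocks
  if (nrow(blocks) == 0L) stop("no blocks to simulate", call. = FALSE)

  var_rows <- list()
  cols <- list()
  ld_pairs <- list()
  block_rsids <- vector("list", nrow(blocks))
  counter <- 0L
  for (k in seq_len(nrow(blocks))) {
    bk <- blocks[k, ]
    mat <- generate_block(cfg$n_haplotypes, bk$n_variants, bk$r2_target,
                          cfg$allele_freq_range)
    rsids <- sprintf("rs%07d", counter + seq_len(bk$n_variants))
    counter <- counter + bk$n_variants
    block_rsids[[k]] <- rsids
    pos <- bk$start + (seq_len(bk$n_variants) - 1L) * bk$spacing_bp
    var_rows[[k]] <- data.frame(
      rsid = rsids, chrom = bk$chrom, pos = pos,
      ref = "A", alt = "G", stringsAsFactors = FALSE
    )
    cols[[k]] <- mat
    if (bk$n_variants >= 2L) {
      for (a in seq_len(bk$n_variants - 1L)) {
        for (b in seq((a + 1L), bk$n_variants)) {
          r2 <- stats::cor(mat[, a], mat[, b])^2
          regime <- if (bk$r2_target >= 0.8) "high" else "low"
          if (regime == "high" && r2 <= 0.9) {
            stop("margin violation: high-LD block realized r2 <= 0.9",
                 call. = FALSE)
          }
          if (regime == "low" && r2 >= 0.7) {
            stop("margin violation: low-LD block realized r2 >= 0.7",
                 call. = FALSE)
          }
          ld_pairs[[length(ld_pairs) + 1L]] <- data.frame(
            block = k, rsid_a = rsids[a], rsid_b = rsids[b],
            r2_realized = r2, r2_regime = regime, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  variants <- do.call(rbind, var_rows)
  hap <- do.call(cbind, cols)
  colnames(hap) <- variants$rsid
  panel <- haplotype_panel(variants, haplotypes = hap,
                           population_tag = "synthetic EUR-like")
  blocks$rsids <- I(block_rsids)
  truth <- list(
    blocks = blocks,
    ld_pairs = if (length(ld_pairs)) do.call(rbind, ld_pairs) else NULL
  )
  list(panel = panel, truth = truth)
}

# log-uniform draw on [lo, hi)
rloguni <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Simulate paired summary statistics with planted trios and distractors
#'
#' Each planted block yields one microbe record (p log-uniform on
#' \[1e-14, 1e-7)) and one metabolite record (p on \[1e-14, 1e-6)) on two
#' block variants whose realized r² exceeds 0.8 within 250 kb. Distractor
#' blocks violate exactly one condition: `below_threshold` draws the
#' microbe p log-uniformly on \[2e-6, 1e-4\] (above the 1e-6 threshold,
#' with margin); `low_ld` uses two independent variants (r² about
#' 1/n_haplotypes); `far_apart` places the pair 300 kb apart. Trait names
#' come from the packaged taxon/metabolite pools, one distinct pair per
#' unit.
#'
#' @param panel,truth output of [simulate_panel()].
#' @param cfg the same [sim_config()].
#' @return list with `microbe` and `metab` (validated association
#'   data.frames) and `truth` extended with `expected_trios` (planted
#'   gene/microbe/metabolite keys) and per-unit record metadata.
#' @export
simulate_sumstats <- function(panel, truth, cfg) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  blocks <- truth$blocks
  n_units <- nrow(blocks)
  taxa <- taxon_names()
  mets <- metabolite_names()
  if (n_units > length(taxa)) {
    taxa <- paste(rep(taxa, length.out = n_units),
                  rep(seq_len(ceiling(n_units / length(taxa))),
                      each = length(taxa))[seq_len(n_units)])
  }
  if (n_units > length(mets)) {
    mets <- paste(rep(mets, length.out = n_units),
                  rep(seq_len(ceiling(n_units / length(mets))),
                      each = length(mets))[seq_len(n_units)])
  }

  micro_rows <- list()
  metab_rows <- list()
  units <- list()
  for (k in seq_len(n_units)) {
    bk <- blocks[k, ]
    rsids <- bk$rsids[[1]]
    if (length(rsids) < 2L) {
      stop("each simulated unit needs >= 2 block variants", call. = FALSE)
    }
    vi <- match(rsids[1:2], panel$variants$rsid)
    microbe_p <- if (bk$role == "below_threshold") {
      rloguni(1, 2e-6, 1e-4)
    } else {
      rloguni(1, 1e-14, 1e-7)
    }
    metab_p <- rloguni(1, 1e-14, 1e-6)
    micro_rows[[k]] <- data.frame(
      rsid = rsids[1], chrom = bk$chrom, pos = panel$variants$pos[vi[1]],
      effect_allele = "G", pvalue = microbe_p, trait = taxa[k],
      trait_type = "microbe", study_id = "SIM-MB", stringsAsFactors = FALSE
    )
    metab_rows[[k]] <- data.frame(
      rsid = rsids[2], chrom = bk$chrom, pos = panel$variants$pos[vi[2]],
      effect_allele = "G", pvalue = metab_p, trait = mets[k],
      trait_type = "metabolite", study_id = "SIM-MT", stringsAsFactors = FALSE
    )
    units[[k]] <- data.frame(
      unit = k, role = bk$role, gene = sprintf("GENE%03d", k),
      microbe = taxa[k], metabolite = mets[k],
      microbe_snp = rsids[1], metab_snp = rsids[2],
      microbe_p = microbe_p, metab_p = metab_p,
      chrom = bk$chrom, stringsAsFactors = FALSE
    )
  }
  microbe <- validate_sumstats(do.call(rbind, micro_rows))
  metab <- validate_sumstats(do.call(rbind, metab_rows))
  units <- do.call(rbind, units)
  truth$units <- units
  truth$expected_trios <- units[units$role == "planted",
                                c("gene", "microbe", "metabolite"),
                                drop = FALSE]
  rownames(truth$expected_trios) <- NULL
  list(microbe = microbe, metab = metab, truth = truth)
}

#' Simulate gene models covering each simulated unit
#'
#' One protein-coding gene per unit, spanning its block with a 1 kb pad,
#' named `GENE001`, `GENE002`, ... so the pipeline's nearest-gene call
#' recovers the intended symbol.
#'
#' @param truth truth list from [simulate_sumstats()].
#' @param panel the simulated [haplotype_panel()].
#' @return gene-model data.frame as from [load_genes()].
#' @export
simulate_genes <- function(truth, panel) {
  blocks <- truth$blocks
  rows <- lapply(seq_len(nrow(blocks)), function(k) {
    rsids <- blocks$rsids[[k]]
    pos <- panel$variants$pos[match(rsids, panel$variants$rsid)]
    data.frame(
      name = sprintf("GENE%03d", k), chrom = blocks$chrom[k],
      start = min(pos) - 1000, end = max(pos) + 1000,
      biotype = "protein_coding", stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate a mini disease-link catalog for planted genes
#'
#' Links each planted unit's gene to "asthma" so the end-to-end pipeline
#' flags every recovered planted trio.
#'
#' @param truth truth list from [simulate_sumstats()].
#' @return catalog data.frame as from [load_catalog()].
#' @export
simulate_catalog <- function(truth) {
  planted <- truth$units[truth$units$role == "planted", , drop = FALSE]
  if (nrow(planted) == 0L) {
    return(data.frame(entity = character(0), class = character(0),
                      trait = character(0), provenance = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    entity = planted$gene, class = "gene", trait = "asthma",
    provenance = "synthetic-catalog", stringsAsFactors = FALSE
  )
}

#' One-call synthetic dataset
#'
#' Runs [simulate_panel()], [simulate_sumstats()], [simulate_genes()], and
#' [simulate_catalog()] and returns everything the pipeline consumes,
#' in memory.
#'
#' @param cfg a [sim_config()].
#' @return list with panel, microbe, metab, genes, catalog, truth.
#' @export
simulate_dataset <- function(cfg) {
  sim <- simulate_panel(cfg)
  ss <- simulate_sumstats(sim$panel, sim$truth, cfg)
  genes <- simulate_genes(ss$truth, sim$panel)
  catalog <- simulate_catalog(ss$truth)
  list(panel = sim$panel, microbe = ss$microbe, metab = ss$metab,
       genes = genes, catalog = catalog, truth = ss$truth)
}

#' Write a simulated dataset to disk
#'
#' Materializes panel.vcf, microbe.tsv, metabolite.tsv, genes.bed,
#' catalog.tsv, and truth.json under `out_dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_panel_vcf(sim$panel, file.path(out_dir, "panel.vcf"))
  write_sumstats(sim$microbe, file.path(out_dir, "microbe.tsv"))
  write_sumstats(sim$metab, file.path(out_dir, "metabolite.tsv"))
  bed <- data.frame(chrom = sim$genes$chrom,
                    start = as.integer(sim$genes$start - 1),
                    end = as.integer(sim$genes$end), name = sim$genes$name,
                    biotype = sim$genes$biotype, strand = "+")
  utils::write.table(bed, file.path(out_dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$catalog, file.path(out_dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_out <- list(
    expected_trios = sim$truth$expected_trios,
    units = sim$truth$units
  )
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(out_dir)
}
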