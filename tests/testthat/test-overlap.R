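make_two_layer <- function(panel, m_idx, b_idx) {
  v <- panel$variants
  list(
    microbe = assoc_df(v$rsid[m_idx], v$chrom[m_idx], v$pos[m_idx],
                       1e-8, paste0("Taxon", seq_along(m_idx)), "microbe"),
    metab = assoc_df(v$rsid[b_idx], v$chrom[b_idx], v$pos[b_idx],
                     1e-7, paste0("Met", seq_along(b_idx)), "metabolite")
  )
}

test_that("an exact rsid match yields one exact locus without the panel", {
  microbe <- assoc_df("rs42", 3, 5e6, 1e-9, "Taxon A", "microbe")
  metab <- assoc_df("rs42", 3, 5e6, 1e-7, "Met B", "metabolite")
  loci <- find_overlaps(microbe, metab, panel = NULL)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$mode, "exact")
  expect_equal(loci$r2, 1.0)
  expect_equal(loci$distance_bp, 0)
  validate_loci(loci)
})

test_that("a planted proxy pair becomes one proxy locus at the oracle r2", {
  cfg <- sim_config(seed = 11, planted_trios = 1,
                    distractors = c(below_threshold = 0, low_ld = 0,
                                    far_apart = 0))
  sim <- simulate_panel(cfg)
  rsids <- sim$truth$blocks$rsids[[1]]
  layers <- make_two_layer(sim$panel,
                           match(rsids[1], sim$panel$variants$rsid),
                           match(rsids[2], sim$panel$variants$rsid))
  loci <- find_overlaps(layers$microbe, layers$metab, sim$panel, ld_config())
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$mode, "proxy")
  i <- match(rsids, sim$panel$variants$rsid)
  expect_equal(loci$r2,
               oracle_r2(sim$panel$haplotypes[, i[1]],
                         sim$panel$haplotypes[, i[2]]),
               tolerance = 1e-12)
  validate_loci(loci)
})

test_that("disjoint rsid sets with no cross-pair LD give an empty result", {
  set.seed(21)
  panel <- random_panel(100, 4)
  layers <- make_two_layer(panel, 1, 3) # independent random columns
  # distance within window but LD is finite-sample noise << 0.8
  loci <- find_overlaps(layers$microbe, layers$metab, panel, ld_config())
  expect_equal(nrow(loci), 0L)
})

test_that("output is bounded by the cross product and passes the validator", {
  set.seed(31)
  for (rep in 1:5) {
    panel <- random_panel(40, 10)
    layers <- make_two_layer(panel, 1:4, 5:10)
    cfg <- ld_config(window_bp = 1e5, r2_min = 0.3)
    loci <- find_overlaps(layers$microbe, layers$metab, panel, cfg)
    expect_lte(nrow(loci), nrow(layers$microbe) * nrow(layers$metab))
    validate_loci(loci, cfg)
  }
})

test_that("degenerate limit emits every same-chromosome cross-pair with
           defined LD", {
  set.seed(41)
  panel <- random_panel(30, 6)
  layers <- make_two_layer(panel, 1:3, 4:6)
  cfg <- ld_config(window_bp = 1e9, r2_min = 0)
  loci <- find_overlaps(layers$microbe, layers$metab, panel, cfg)
  # brute force: all 9 cross-pairs qualify unless r2 is exactly 0
  expected <- 0L
  for (i in 1:3) for (j in 4:6) {
    r2 <- oracle_r2(panel$haplotypes[, i], panel$haplotypes[, j])
    if (r2 > 0) expected <- expected + 1L
  }
  expect_equal(nrow(loci), expected)
})

test_that("swapping anchor layer leaves the emitted pair set unchanged", {
  set.seed(51)
  for (rep in 1:5) {
    panel <- random_panel(60, 8)
    layers <- make_two_layer(panel, c(1, 3, 5), c(2, 4, 6, 8))
    cfg <- ld_config(window_bp = 1e5, r2_min = 0.2)
    fwd <- find_overlaps(layers$microbe, layers$metab, panel, cfg)
    # swap roles: relabel layers and compare the set of (rsid, rsid) pairs
    microbe_as_metab <- layers$microbe
    microbe_as_metab$trait_type <- "metabolite"
    metab_as_microbe <- layers$metab
    metab_as_microbe$trait_type <- "microbe"
    rev <- find_overlaps(metab_as_microbe, microbe_as_metab, panel, cfg)
    expect_setequal(paste(fwd$microbe_rsid, fwd$metab_rsid),
                    paste(rev$metab_rsid, rev$microbe_rsid))
  }
})

test_that("one anchor with several proxy partners emits one locus per
           partner, and merge_loci collapses them to min p-product", {
  # three variants in near-perfect LD: anchor microbe SNP + two metabolite
  # partners tagging the same signal for the same trait pair
  n <- 100
  set.seed(61)
  founder <- rbinom(n, 1, 0.5)
  flip1 <- founder; flip1[1] <- 1L - flip1[1]
  flip2 <- founder; flip2[2] <- 1L - flip2[2]
  panel <- haplotype_panel(
    data.frame(rsid = c("rsM", "rsP1", "rsP2"), chrom = "1",
               pos = c(1e6, 1e6 + 1e4, 1e6 + 2e4), ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    haplotypes = cbind(founder, flip1, flip2)
  )
  microbe <- assoc_df("rsM", 1, 1e6, 1e-9, "TaxonX", "microbe")
  metab <- assoc_df(c("rsP1", "rsP2"), 1, c(1e6 + 1e4, 1e6 + 2e4),
                    c(1e-7, 1e-8), "MetY", "metabolite")
  loci <- find_overlaps(microbe, metab, panel, ld_config())
  expect_equal(nrow(loci), 2L)
  merged <- merge_loci(loci, panel, ld_config())
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$metab_rsid, "rsP2") # smaller p-product wins
})

test_that("records absent from the panel still form exact loci", {
  microbe <- assoc_df("rsGhost", 1, 1e6, 1e-9, "TaxonA", "microbe")
  metab <- assoc_df("rsGhost", 1, 1e6, 1e-8, "MetB", "metabolite")
  panel <- random_panel(10, 2)
  loci <- find_overlaps(microbe, metab, panel, ld_config())
  expect_equal(loci$mode, "exact")
})
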