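test_that("load_panel expands phased GTs and skips unusable records", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  recs <- c(
    vcf_record(1, 100, "rs1", "A", "G", c("0|1", "1|1")),
    vcf_record(1, 200, "rs2", "C", "T", c("0|0", "0|1")),
    vcf_record(1, 300, "rs3", "A", "AT", c("0|1", "0|0")),   # indel
    vcf_record(1, 400, "rs4", "G", "A,T", c("0|1", "0|2")),  # multi-allelic
    vcf_record(1, 500, "rs5", "T", "C", c(".|.", "0|1"))     # missing
  )
  write_test_vcf(tmp, recs)
  expect_message(panel <- load_panel(tmp), "skipped 3")
  expect_equal(nrow(panel$variants), 2L)
  expect_equal(dim(panel$haplotypes), c(4L, 2L))  # 2 samples -> 4 haplotypes
  expect_equal(unname(panel$haplotypes[, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(panel$ld_mode, "phased")
})

test_that("unphased genotypes error in strict mode, load in dosage mode", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(tmp, c(
    vcf_record(1, 100, "rs1", "A", "G", c("0/1", "1|1")),
    vcf_record(1, 200, "rs2", "C", "T", c("0/0", "0/1"))
  ))
  expect_error(load_panel(tmp), "unphased")
  panel <- load_panel(tmp, mode = "dosage")
  expect_equal(panel$ld_mode, "dosage")
  expect_equal(unname(panel$dosages[, 1]), c(1L, 2L))
})

test_that("load_panel errors when no usable variants remain", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(tmp, vcf_record(1, 100, "rs1", "A", "AT", c("0|1", "0|0")))
  expect_error(suppressMessages(load_panel(tmp)), "no usable")
})

test_that("compute_r2 reproduces hand-checkable cases", {
  # identical columns -> perfect LD
  hap <- cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  expect_equal(compute_r2(panel_from_matrix(hap), "rsT001", "rsT002"), 1)

  # (0,0,1,1) vs (0,1,0,1): pAB = pA*pB exactly -> r2 = 0
  hap <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  expect_equal(compute_r2(panel_from_matrix(hap), "rsT001", "rsT002"), 0)

  # monomorphic variant -> undefined, not zero
  hap <- cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L))
  expect_error(compute_r2(panel_from_matrix(hap), "rsT001", "rsT002"),
               "monomorphic")

  # different chromosomes refuse
  panel <- panel_from_matrix(cbind(c(0L, 1L), c(1L, 0L)),
                             chrom = c("1", "2"))
  expect_error(compute_r2(panel, "rsT001", "rsT002"), "chromosomes")
})

test_that("compute_r2 matches the haplotype-count oracle, is symmetric, and
           is invariant to allele-encoding swaps", {
  set.seed(101)
  for (rep in 1:25) {
    panel <- random_panel(8, 6)
    for (a in 1:5) for (b in (a + 1):6) {
      ra <- panel$variants$rsid[a]
      rb <- panel$variants$rsid[b]
      r2 <- compute_r2(panel, ra, rb)
      expect_equal(r2, oracle_r2(panel$haplotypes[, a], panel$haplotypes[, b]),
                   tolerance = 1e-12)
      expect_identical(r2, compute_r2(panel, rb, ra))
    }
    # complementing a column (ref/alt swap) leaves r2 unchanged
    flipped <- panel
    flipped$haplotypes[, 1] <- 1L - flipped$haplotypes[, 1]
    expect_equal(
      compute_r2(flipped, flipped$variants$rsid[1], flipped$variants$rsid[2]),
      compute_r2(panel, panel$variants$rsid[1], panel$variants$rsid[2]),
      tolerance = 1e-12
    )
  }
})

test_that("find_proxies applies window and r2 rules with strictness at the
           stated boundaries", {
  # anchor plus: perfect proxy in window, distractor on another chromosome,
  # candidate exactly at the window edge, candidate just past it
  hap_anchor <- c(0L, 0L, 1L, 1L, 0L, 1L)
  hap <- cbind(hap_anchor, hap_anchor, hap_anchor, hap_anchor,
               c(0L, 1L, 0L, 1L, 1L, 0L))
  panel <- haplotype_panel(
    data.frame(
      rsid = c("rsA", "rsIn", "rsEdge", "rsPast", "rsOther"),
      chrom = c("1", "1", "1", "1", "2"),
      pos = c(1e6, 1e6 + 5e4, 1e6 + 250000, 1e6 + 250001, 1e6 + 100),
      ref = "A", alt = "G", stringsAsFactors = FALSE
    ),
    haplotypes = hap
  )
  anchor <- list(rsid = "rsA", chrom = "1", pos = 1e6)
  cands <- assoc_df(c("rsIn", "rsEdge", "rsPast", "rsOther"),
                    c(1, 1, 1, 2),
                    c(1e6 + 5e4, 1e6 + 250000, 1e6 + 250001, 1e6 + 100),
                    1e-8, paste0("M", 1:4), "metabolite")
  px <- find_proxies(panel, anchor, cands, ld_config())
  # distance 250000 included, 250001 excluded, other chromosome excluded
  expect_setequal(px$rsid_b, c("rsIn", "rsEdge"))
  expect_equal(px$r2, c(1, 1))

  # r2 exactly at r2_min is excluded (strict >)
  px2 <- find_proxies(panel, anchor, cands, ld_config(r2_min = 1))
  expect_equal(nrow(px2), 0L)

  # absent anchor: empty result with a message, not an error
  expect_message(
    none <- find_proxies(panel, list(rsid = "rsNone", chrom = "1", pos = 1e6),
                         cands),
    "absent"
  )
  expect_equal(nrow(none), 0L)
})

test_that("find_proxies orders by descending r2, then distance, then rsid", {
  set.seed(202)
  n <- 60
  founder <- rbinom(n, 1, 0.5)
  noisy <- function(k) { # k flips -> decreasing LD
    col <- founder
    idx <- sample(n, k)
    col[idx] <- 1L - col[idx]
    col
  }
  tied <- noisy(2) # shared by rsB and rsD: exact r2 tie
  hap <- cbind(founder, tied, noisy(6), tied)
  panel <- haplotype_panel(
    data.frame(rsid = c("rsA", "rsB", "rsC", "rsD"), chrom = "1",
               pos = c(1e6, 1e6 + 2e4, 1e6 + 1e4, 1e6 + 3e4),
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    haplotypes = hap
  )
  anchor <- list(rsid = "rsA", chrom = "1", pos = 1e6)
  cands <- assoc_df(c("rsB", "rsC", "rsD"), 1,
                    c(1e6 + 2e4, 1e6 + 1e4, 1e6 + 3e4),
                    1e-8, paste0("M", 1:3), "metabolite")
  px <- find_proxies(panel, anchor, cands, ld_config(r2_min = 0.1))
  expect_equal(px$r2, sort(px$r2, decreasing = TRUE))
  # rsB and rsD tie exactly on r2; smaller distance (rsB) comes first
  expect_equal(px$rsid_b[1:2], c("rsB", "rsD"))
})

test_that("proxy sets are monotone in window size and r2 threshold", {
  set.seed(303)
  for (rep in 1:10) {
    panel <- random_panel(30, 8)
    anchor <- list(rsid = panel$variants$rsid[1], chrom = "1",
                   pos = panel$variants$pos[1])
    cands <- assoc_df(panel$variants$rsid[-1], 1, panel$variants$pos[-1],
                      1e-8, paste0("M", 1:7), "metabolite")
    base <- find_proxies(panel, anchor, cands, ld_config(3e4, 0.5))
    wider <- find_proxies(panel, anchor, cands, ld_config(9e4, 0.5))
    looser <- find_proxies(panel, anchor, cands, ld_config(3e4, 0.1))
    expect_true(all(base$rsid_b %in% wider$rsid_b))
    expect_true(all(base$rsid_b %in% looser$rsid_b))
  }
})

test_that("a planted high-LD proxy is recovered exactly", {
  set.seed(404)
  cfg <- sim_config(seed = 404, planted_trios = 1,
                    distractors = c(below_threshold = 0, low_ld = 0,
                                    far_apart = 0))
  sim <- simulate_panel(cfg)
  rsids <- sim$truth$blocks$rsids[[1]]
  v <- sim$panel$variants
  anchor <- list(rsid = rsids[1], chrom = v$chrom[v$rsid == rsids[1]],
                 pos = v$pos[v$rsid == rsids[1]])
  # candidates: the true partner plus a same-position distractor on chrom 2
  cands <- assoc_df(c(rsids[2], "rsFake"), c(anchor$chrom, "2"),
                    c(v$pos[v$rsid == rsids[2]], anchor$pos),
                    1e-9, c("M1", "M2"), "metabolite")
  px <- suppressMessages(find_proxies(sim$panel, anchor, cands))
  expect_equal(px$rsid_b, rsids[2])
  expect_equal(px$r2, sim$truth$ld_pairs$r2_realized[1], tolerance = 1e-12)
  expect_gt(px$r2, 0.9)
})

test_that("VCF write/load round-trips a phased panel", {
  set.seed(505)
  panel <- random_panel(20, 5)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(panel, tmp)
  back <- load_panel(tmp)
  expect_equal(back$variants[, c("rsid", "chrom", "pos", "ref", "alt")],
               panel$variants[, c("rsid", "chrom", "pos", "ref", "alt")])
  expect_equal(unname(back$haplotypes), unname(panel$haplotypes))
})
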