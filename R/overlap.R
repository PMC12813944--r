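#' Join microbe and metabolite associations into overlap loci
#'
#' The core cross-referencing step: a locus overlaps when a filtered
#' gene-microbe association and a filtered gene-metabolite association share
#' the same lead SNP (`mode = "exact"`) or their lead SNPs are LD proxies
#' within the configured window (`mode = "proxy"`). Exact matches are found
#' by rsid equality first and never consult the panel, so they survive even
#' for variants missing from the panel. Remaining microbe records are then
#' anchored for a proxy search among remaining metabolite records; when one
#' anchor has several proxy partners, one locus per partner is emitted.
#'
#' @param microbe filtered microbe-layer association data.frame.
#' @param metab filtered metabolite-layer association data.frame.
#' @param panel a [haplotype_panel()] used for proxy LD.
#' @param cfg an [ld_config()].
#' @return data.frame of overlap loci with columns chrom, microbe_rsid,
#'   microbe_pos, microbe_trait, microbe_p, metab_rsid, metab_pos,
#'   metab_trait, metab_p, mode, r2, distance_bp, ordered by
#'   (chrom, min pos, rsids).
#' @export
find_overlaps <- function(microbe, metab, panel, cfg = ld_config()) {
  stopifnot(inherits(cfg, "ld_config"))
  loci <- list()

  locus_row <- function(m, b, mode, r2, dist) {
    data.frame(
      chrom = m$chrom,
      microbe_rsid = m$rsid, microbe_pos = m$pos,
      microbe_trait = m$trait, microbe_p = m$pvalue,
      metab_rsid = b$rsid, metab_pos = b$pos,
      metab_trait = b$trait, metab_p = b$pvalue,
      mode = mode, r2 = r2, distance_bp = dist,
      stringsAsFactors = FALSE
    )
  }

  # exact: every cross-pair sharing an rsid
  shared <- intersect(microbe$rsid, metab$rsid)
  for (rs in shared) {
    mi <- which(microbe$rsid == rs)
    bi <- which(metab$rsid == rs)
    for (i in mi) for (j in bi) {
      loci[[length(loci) + 1L]] <-
        locus_row(microbe[i, ], metab[j, ], "exact", 1.0, 0)
    }
  }

  # proxy: remaining microbe anchors vs remaining metabolite candidates
  m_rem <- microbe[!(microbe$rsid %in% shared), , drop = FALSE]
  b_rem <- metab[!(metab$rsid %in% shared), , drop = FALSE]
  if (nrow(m_rem) && nrow(b_rem) && !is.null(panel)) {
    for (i in seq_len(nrow(m_rem))) {
      anchor <- m_rem[i, ]
      px <- find_proxies(panel, anchor, b_rem, cfg)
      for (k in seq_len(nrow(px))) {
        j <- which(b_rem$rsid == px$rsid_b[k])
        for (jj in j) {
          loci[[length(loci) + 1L]] <-
            locus_row(anchor, b_rem[jj, ], "proxy", px$r2[k], px$distance_bp[k])
        }
      }
    }
  }

  if (!length(loci)) {
    return(data.frame(
      chrom = character(0), microbe_rsid = character(0),
      microbe_pos = numeric(0), microbe_trait = character(0),
      microbe_p = numeric(0), metab_rsid = character(0),
      metab_pos = numeric(0), metab_trait = character(0),
      metab_p = numeric(0), mode = character(0), r2 = numeric(0),
      distance_bp = numeric(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, loci)
  min_pos <- pmin(out$microbe_pos, out$metab_pos)
  out <- out[order(chrom_rank(out$chrom), min_pos,
                   out$microbe_rsid, out$metab_rsid,
                   out$microbe_trait, out$metab_trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate emitted overlap loci against their mode invariants
#'
#' Re-checks every locus: exact loci must share an rsid and carry r2 = 1,
#' distance 0; proxy loci must satisfy r2 > r2_min and distance <=
#' window_bp. Used as a validator pass in tests and in the pipeline.
#'
#' @param loci output of [find_overlaps()].
#' @param cfg the [ld_config()] used to build them.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_loci <- function(loci, cfg = ld_config()) {
  if (nrow(loci) == 0L) return(invisible(TRUE))
  ex <- loci$mode == "exact"
  if (any(ex & (loci$microbe_rsid != loci$metab_rsid | loci$r2 != 1 |
                  loci$distance_bp != 0))) {
    stop("exact locus violates its invariant", call. = FALSE)
  }
  px <- loci$mode == "proxy"
  if (any(px & (loci$r2 <= cfg$r2_min | loci$distance_bp > cfg$window_bp))) {
    stop("proxy locus violates its invariant", call. = FALSE)
  }
  invisible(TRUE)
}

#' Collapse redundant loci tagging one region
#'
#' Several SNP pairs can tag the same underlying signal. Two loci collapse
#' when they involve the same (microbe trait, metabolite trait) pair and
#' their lead SNPs on each side are identical or mutual panel proxies under
#' `cfg`. Within each group, the locus with the smallest product of the two
#' p-values is kept. Enabled by default in [run_pipeline()].
#'
#' @param loci output of [find_overlaps()].
#' @param panel a [haplotype_panel()] (may be `NULL`: only identical-rsid
#'   loci then collapse).
#' @param cfg an [ld_config()].
#' @return data.frame of merged loci, same columns and ordering as input.
#' @export
merge_loci <- function(loci, panel = NULL, cfg = ld_config()) {
  if (nrow(loci) <= 1L) return(loci)

  same_signal <- function(rs1, pos1, rs2, pos2, chrom) {
    if (rs1 == rs2) return(TRUE)
    if (is.null(panel)) return(FALSE)
    if (abs(pos1 - pos2) > cfg$window_bp) return(FALSE)
    r2 <- tryCatch(compute_r2(panel, rs1, rs2), error = function(e) NA_real_)
    !is.na(r2) && r2 > cfg$r2_min
  }

  n <- nrow(loci)
  group <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (group[j] == group[i]) next
      if (loci$microbe_trait[i] != loci$microbe_trait[j] ||
          loci$metab_trait[i] != loci$metab_trait[j] ||
          loci$chrom[i] != loci$chrom[j]) next
      if (same_signal(loci$microbe_rsid[i], loci$microbe_pos[i],
                      loci$microbe_rsid[j], loci$microbe_pos[j],
                      loci$chrom[i]) &&
          same_signal(loci$metab_rsid[i], loci$metab_pos[i],
                      loci$metab_rsid[j], loci$metab_pos[j],
                      loci$chrom[i])) {
        group[group == group[j]] <- group[i]
      }
    }
  }
  keep <- vapply(split(seq_len(n), group), function(idx) {
    idx[which.min(loci$microbe_p[idx] * loci$metab_p[idx])]
  }, integer(1))
  out <- loci[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
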