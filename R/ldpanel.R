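#' LD search configuration
#'
#' Proxy search keeps candidate variants at most `window_bp` base pairs from
#' the anchor (inclusive boundary) with pairwise r-squared strictly greater
#' than `r2_min`. Defaults reproduce the conventional tagging definition
#' used in cross-trait locus overlap: a 250 kb window and r² > 0.8.
#'
#' @param window_bp maximum base-pair separation (inclusive).
#' @param r2_min minimum r²; proxies must exceed this strictly.
#' @return An object of class `ld_config`.
#' @export
ld_config <- function(window_bp = 250000, r2_min = 0.8) {
  stopifnot(
    is.numeric(window_bp), length(window_bp) == 1L, window_bp > 0,
    is.numeric(r2_min), length(r2_min) == 1L, r2_min >= 0, r2_min <= 1
  )
  structure(list(window_bp = window_bp, r2_min = r2_min), class = "ld_config")
}

#' @export
print.ld_config <- function(x, ...) {
  cat(sprintf("ld_config: window <= %d bp, r2 > %g\n",
              as.integer(x$window_bp), x$r2_min))
  invisible(x)
}

#' Construct a haplotype reference panel
#'
#' A panel holds an ordered variant index and a binary allele matrix with
#' one row per phased haplotype (two per diploid sample) and one column per
#' variant; entry 1 means the alternate allele. An unphased panel loaded in
#' dosage mode instead carries a 0/1/2 genotype-dosage matrix with one row
#' per sample; LD is then the squared Pearson correlation of dosages.
#'
#' @param variants data.frame with columns rsid, chrom, pos, ref, alt.
#' @param haplotypes binary matrix, haplotypes x variants (phased mode).
#' @param dosages 0/1/2 matrix, samples x variants (dosage mode).
#' @param build genome-build tag.
#' @param population_tag free-text panel label.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, haplotypes = NULL, dosages = NULL,
                            build = "GRCh37", population_tag = "EUR-like") {
  stopifnot(is.data.frame(variants),
            all(c("rsid", "chrom", "pos", "ref", "alt") %in% names(variants)))
  mat <- if (!is.null(haplotypes)) haplotypes else dosages
  if (is.null(mat)) stop("panel needs a haplotype or dosage matrix", call. = FALSE)
  stopifnot(is.matrix(mat), ncol(mat) == nrow(variants))
  if (!is.null(haplotypes)) {
    if (!all(haplotypes %in% c(0L, 1L))) {
      stop("haplotype matrix entries must be 0/1", call. = FALSE)
    }
    if (nrow(haplotypes) < 2L) stop("panel needs >= 2 haplotypes", call. = FALSE)
  } else if (!all(dosages %in% c(0L, 1L, 2L))) {
    stop("dosage matrix entries must be 0/1/2", call. = FALSE)
  }
  variants$chrom <- normalize_chrom(variants$chrom)
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  mat <- mat[, ord, drop = FALSE]
  colnames(mat) <- variants$rsid
  rownames(variants) <- NULL
  if (anyDuplicated(variants$rsid)) {
    stop("duplicate rsid in panel variant index", call. = FALSE)
  }
  structure(
    list(
      variants = variants,
      haplotypes = if (!is.null(haplotypes)) mat else NULL,
      dosages = if (is.null(haplotypes)) mat else NULL,
      ld_mode = if (!is.null(haplotypes)) "phased" else "dosage",
      build = build,
      population_tag = population_tag
    ),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  mat <- panel_matrix(x)
  cat(sprintf(
    "haplotype_panel (%s): %d variants x %d %s [%s, %s]\n",
    x$ld_mode, nrow(x$variants), nrow(mat),
    if (x$ld_mode == "phased") "haplotypes" else "samples",
    x$build, x$population_tag
  ))
  invisible(x)
}

panel_matrix <- function(panel) {
  if (panel$ld_mode == "phased") panel$haplotypes else panel$dosages
}

panel_column <- function(panel, rsid) {
  j <- match(rsid, panel$variants$rsid)
  if (is.na(j)) stop("variant not in panel: ", rsid, call. = FALSE)
  panel_matrix(panel)[, j]
}

#' Load a phased haplotype panel from a VCF file
#'
#' Reads a VCF 4.x file, keeps biallelic SNP records, and expands phased
#' diploid GT fields into a 2-per-sample haplotype matrix. Multi-allelic
#' records, indels, and records with missing genotypes are skipped with a
#' message reporting the count. An unphased genotype (separator `/`) is an
#' error in strict mode; `mode = "dosage"` instead falls back to 0/1/2
#' genotype dosages for the whole panel, clearly labeled on the object.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param mode `"strict"` (phased haplotypes, default) or `"dosage"`.
#' @param build genome-build tag recorded on the panel.
#' @param population_tag label recorded on the panel.
#' @return A [haplotype_panel()].
#' @export
load_panel <- function(path, mode = c("strict", "dosage"),
                       build = "GRCh37", population_tag = "EUR-like") {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("panel VCF not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path, genome = build)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  is_snp <- n_alt == 1L & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  has_missing <- apply(gt, 1L, function(g) any(grepl("\\.", g)))
  keep <- is_snp & !has_missing
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("load_panel: skipped %d non-SNP/multi-allelic/missing record(s)",
                    n_skipped))
  }
  if (!any(keep)) stop("no usable biallelic SNPs in panel", call. = FALSE)
  gt <- gt[keep, , drop = FALSE]

  unphased <- grepl("/", gt, fixed = TRUE)
  if (mode == "strict" && any(unphased)) {
    bad <- which(matrix(unphased, nrow = nrow(gt)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unphased genotype '%s' at record %s (sample %s); use mode='dosage' for unphased panels",
      gt[bad[1], bad[2]], rownames(gt)[bad[1]], colnames(gt)[bad[2]]
    ), call. = FALSE)
  }

  variants <- data.frame(
    rsid = rownames(gt),
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep],
    alt = alt[keep],
    stringsAsFactors = FALSE
  )

  split_gt <- function(g) {
    parts <- strsplit(g, "[|/]")
    lens <- lengths(parts)
    if (any(lens != 2L)) stop("non-diploid genotype encountered", call. = FALSE)
    matrix(as.integer(unlist(parts)), nrow = 2L)
  }

  if (mode == "strict") {
    # rows: sample1 hapA, sample1 hapB, sample2 hapA, ...
    hap <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
    for (j in seq_len(nrow(gt))) {
      hap[, j] <- as.vector(split_gt(gt[j, ]))
    }
    if (!all(hap %in% c(0L, 1L))) {
      stop("non-biallelic allele code in GT field", call. = FALSE)
    }
    haplotype_panel(variants, haplotypes = hap,
                    build = build, population_tag = population_tag)
  } else {
    dos <- matrix(0L, nrow = ncol(gt), ncol = nrow(gt))
    for (j in seq_len(nrow(gt))) {
      dos[, j] <- colSums(split_gt(gt[j, ]))
    }
    haplotype_panel(variants, dosages = dos,
                    build = build, population_tag = population_tag)
  }
}

#' Pairwise linkage disequilibrium r-squared
#'
#' For a phased panel, r² is the haplotype-frequency measure
#' \deqn{r^2 = (p_{AB} - p_A p_B)^2 / (p_A(1-p_A) \, p_B(1-p_B))}
#' with `p_AB` the joint alternate-allele haplotype frequency — equal to the
#' squared Pearson correlation of the two 0/1 haplotype columns. For a
#' dosage-mode panel it is the squared Pearson correlation of 0/1/2
#' dosages. Either variant being monomorphic in the panel leaves r²
#' undefined (zero denominator) and raises an error rather than returning
#' 0, so undefined LD can neither create nor destroy proxies.
#'
#' @param panel a [haplotype_panel()].
#' @param rsid_a,rsid_b variant identifiers present in the panel.
#' @return r² in \[0, 1\].
#' @export
compute_r2 <- function(panel, rsid_a, rsid_b) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ia <- match(rsid_a, panel$variants$rsid)
  ib <- match(rsid_b, panel$variants$rsid)
  if (is.na(ia)) stop("variant not in panel: ", rsid_a, call. = FALSE)
  if (is.na(ib)) stop("variant not in panel: ", rsid_b, call. = FALSE)
  if (panel$variants$chrom[ia] != panel$variants$chrom[ib]) {
    stop("variants on different chromosomes: ", rsid_a, ", ", rsid_b,
         call. = FALSE)
  }
  mat <- panel_matrix(panel)
  a <- mat[, ia]
  b <- mat[, ib]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    mono <- c(rsid_a, rsid_b)[c(stats::var(a) == 0, stats::var(b) == 0)]
    stop("LD undefined: monomorphic variant(s) in panel: ",
         paste(mono, collapse = ", "), call. = FALSE)
  }
  r2 <- stats::cor(a, b)^2
  # clamp tiny floating overshoot
  min(max(r2, 0), 1)
}

#' Find LD proxies for an anchor variant
#'
#' Returns the candidates on the anchor's chromosome whose distance from
#' the anchor is at most `window_bp` (inclusive) and whose panel r² with
#' the anchor is strictly greater than `r2_min`, sorted by descending r²,
#' ties broken by ascending distance then rsid. Candidates absent from the
#' panel or monomorphic are skipped (their LD is unknown or undefined).
#'
#' @param panel a [haplotype_panel()].
#' @param anchor one-row association data.frame (or list) with rsid, chrom, pos.
#' @param candidates association data.frame of candidate records.
#' @param cfg an [ld_config()].
#' @return data.frame with columns rsid_a (anchor), rsid_b, r2, distance_bp.
#' @export
find_proxies <- function(panel, anchor, candidates, cfg = ld_config()) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(cfg, "ld_config"))
  empty <- data.frame(rsid_a = character(0), rsid_b = character(0),
                      r2 = numeric(0), distance_bp = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.na(match(anchor$rsid, panel$variants$rsid))) {
    message("find_proxies: anchor absent from panel: ", anchor$rsid)
    return(empty)
  }
  if (nrow(candidates) == 0L) return(empty)
  anchor_chrom <- normalize_chrom(anchor$chrom)
  dist <- abs(candidates$pos - anchor$pos)
  ok <- normalize_chrom(candidates$chrom) == anchor_chrom &
    dist <= cfg$window_bp &
    candidates$rsid != anchor$rsid
  cand <- candidates[ok, , drop = FALSE]
  dist <- dist[ok]
  if (nrow(cand) == 0L) return(empty)

  r2 <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r2[i] <- tryCatch(
      compute_r2(panel, anchor$rsid, cand$rsid[i]),
      error = function(e) NA_real_
    )
  }
  keep <- !is.na(r2) & r2 > cfg$r2_min
  out <- data.frame(
    rsid_a = rep(anchor$rsid, sum(keep)),
    rsid_b = cand$rsid[keep],
    r2 = r2[keep],
    distance_bp = dist[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$r2, out$distance_bp, out$rsid_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a haplotype panel to a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with phased GT fields, the inverse of
#' [load_panel()] in strict mode. Used by the synthetic-data generator and
#' the packaged fixture; not a general-purpose VCF writer.
#'
#' @param panel a phased [haplotype_panel()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (panel$ld_mode != "phased") {
    stop("only phased panels can be written as VCF", call. = FALSE)
  }
  hap <- panel$haplotypes
  n_samples <- nrow(hap) %/% 2L
  v <- panel$variants
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=trioscan synthetic panel (%s)", panel$population_tag),
    sprintf("##reference=%s", panel$build),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  odd <- seq(1L, nrow(hap), by = 2L)
  body <- vapply(seq_len(nrow(v)), function(j) {
    gts <- paste(hap[odd, j], hap[odd + 1L, j], sep = "|")
    paste(c(v$chrom[j], sprintf("%d", as.integer(v$pos[j])), v$rsid[j],
            v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
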