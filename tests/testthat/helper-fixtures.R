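# Shared fixture builders and independent oracles. Everything is built in
# code at test time; no binary files.

# minimal validated association data.frame
assoc_df <- function(rsid, chrom, pos, pvalue, trait, trait_type,
                     effect_allele = "G", study_id = "TEST") {
  validate_sumstats(data.frame(
    rsid = rsid, chrom = as.character(chrom), pos = pos,
    effect_allele = effect_allele, pvalue = pvalue, trait = trait,
    trait_type = trait_type, study_id = study_id,
    stringsAsFactors = FALSE
  ))
}

# panel from an explicit haplotype matrix (haplotypes x variants)
panel_from_matrix <- function(hap, chrom = "1", pos = NULL, rsid = NULL) {
  m <- ncol(hap)
  if (is.null(pos)) pos <- seq(1e6, by = 1e4, length.out = m)
  if (is.null(rsid)) rsid <- sprintf("rsT%03d", seq_len(m))
  haplotype_panel(
    data.frame(rsid = rsid, chrom = chrom, pos = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    haplotypes = hap
  )
}

# random polymorphic panel: n_hap haplotypes, m variants, all on one chrom
random_panel <- function(n_hap, m, chrom = "1") {
  hap <- matrix(0L, n_hap, m)
  for (j in seq_len(m)) {
    repeat {
      col <- rbinom(n_hap, 1L, runif(1, 0.2, 0.8))
      if (var(col) > 0) break
    }
    hap[, j] <- col
  }
  panel_from_matrix(hap, chrom = chrom)
}

# independent LD oracle: tabulate the four haplotype counts n00,n01,n10,n11
# and evaluate r2 = (pAB - pA pB)^2 / (pA(1-pA) pB(1-pB)) directly
oracle_r2 <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1)
  pAB <- n11 / n
  pA <- sum(a) / n
  pB <- sum(b) / n
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# independent nearest-gene oracle: exhaustive scan, same tie-break rule
oracle_nearest <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  if (any(g$biotype == "protein_coding")) {
    g <- g[g$biotype == "protein_coding", , drop = FALSE]
  }
  best <- NULL
  for (i in seq_len(nrow(g))) {
    d <- if (pos >= g$start[i] && pos <= g$end[i]) 0 else
      min(abs(pos - g$start[i]), abs(pos - g$end[i]))
    cand <- list(name = g$name[i], dist = d, biotype = g$biotype[i])
    if (is.null(best) || d < best$dist ||
        (d == best$dist && cand$biotype == "protein_coding" &&
           best$biotype != "protein_coding") ||
        (d == best$dist && cand$biotype == best$biotype &&
           cand$name < best$name)) {
      best <- cand
    }
  }
  best
}

# small gene table builder
gene_df <- function(name, chrom, start, end, biotype = "protein_coding") {
  data.frame(name = name, chrom = as.character(chrom), start = start,
             end = end, biotype = biotype, stringsAsFactors = FALSE)
}

# write a tiny VCF by hand (independent of write_panel_vcf)
write_test_vcf <- function(path, records, samples = c("SA", "SB")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
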