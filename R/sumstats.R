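#' Threshold configuration for suggestive-significance filtering
#'
#' The screen keeps associations whose p-value falls strictly below a
#' per-layer suggestive threshold. Defaults follow the usual mbQTL/mQTL
#' convention: 1e-6 for gene-microbe associations and 1e-5 for
#' gene-metabolite associations, both more lenient than genome-wide
#' significance (5e-8) so pleiotropic loci are not lost when only one layer
#' reaches the stringent level.
#'
#' @param alpha_microbe p-value threshold for gene-microbe records.
#' @param alpha_metabolite p-value threshold for gene-metabolite records.
#' @return An object of class `threshold_config`.
#' @export
#' @examples
#' threshold_config()
#' threshold_config(alpha_microbe = 5e-8)
threshold_config <- function(alpha_microbe = 1e-6, alpha_metabolite = 1e-5) {
  stopifnot(
    is.numeric(alpha_microbe), length(alpha_microbe) == 1L,
    alpha_microbe > 0, alpha_microbe < 1,
    is.numeric(alpha_metabolite), length(alpha_metabolite) == 1L,
    alpha_metabolite > 0, alpha_metabolite < 1
  )
  structure(
    list(alpha_microbe = alpha_microbe, alpha_metabolite = alpha_metabolite),
    class = "threshold_config"
  )
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf(
    "threshold_config: p < %g (microbe), p < %g (metabolite)\n",
    x$alpha_microbe, x$alpha_metabolite
  ))
  invisible(x)
}

SUMSTATS_COLUMNS <- c("rsid", "chrom", "pos", "effect_allele",
                      "pvalue", "trait", "study_id")

VALID_CHROMS <- c(as.character(1:22), "X")

normalize_chrom <- function(chrom) {
  chrom <- sub("^chr", "", trimws(as.character(chrom)), ignore.case = TRUE)
  toupper_x <- ifelse(tolower(chrom) == "x", "X", chrom)
  toupper_x
}

#' Validate a table of SNP-trait association records
#'
#' Checks every row of a summary-statistics table against the record
#' contract: valid chromosome (1-22 or X, `chr` prefixes stripped),
#' positive 1-based position, single-base effect allele, p-value in (0, 1],
#' non-empty trait, and a `trait_type` of `"microbe"` or `"metabolite"`.
#'
#' @param df data.frame with columns rsid, chrom, pos, effect_allele,
#'   pvalue, trait, study_id (and optionally trait_type).
#' @param trait_type `"microbe"` or `"metabolite"`; applied to all rows when
#'   the table has no trait_type column.
#' @return The validated, normalized data.frame (chromosomes normalized,
#'   pos integer-valued numeric, pvalue numeric).
#' @export
validate_sumstats <- function(df, trait_type = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(SUMSTATS_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("summary-statistics table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$trait_type)) {
    trait_type <- match.arg(trait_type, c("microbe", "metabolite"))
    df$trait_type <- if (nrow(df)) trait_type else character(0)
  }
  if (nrow(df) == 0L) {
    df$pos <- as.numeric(df$pos)
    df$pvalue <- as.numeric(df$pvalue)
    return(df[, c(SUMSTATS_COLUMNS[1:6], "trait_type", "study_id")])
  }

  df$chrom <- normalize_chrom(df$chrom)
  pos <- suppressWarnings(as.numeric(df$pos))
  pval <- suppressWarnings(as.numeric(df$pvalue))

  problems <- character(0)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      problems <<- c(problems, sprintf("row %d: %s", idx, what))
    }
  }
  bad(is.na(df$rsid) | !nzchar(trimws(df$rsid)), "empty rsid")
  bad(!(df$chrom %in% VALID_CHROMS),
      sprintf("invalid chromosome '%s'", df$chrom))
  bad(is.na(pos) | pos < 1 | pos != floor(pos), "unparsable or non-positive position")
  bad(!(toupper(df$effect_allele) %in% c("A", "C", "G", "T")),
      sprintf("invalid effect allele '%s'", df$effect_allele))
  bad(is.na(pval) | pval <= 0 | pval > 1, "p-value not in (0, 1]")
  bad(is.na(df$trait) | !nzchar(trimws(df$trait)), "empty trait")
  bad(!(df$trait_type %in% c("microbe", "metabolite")),
      sprintf("invalid trait_type '%s'", df$trait_type))

  if (length(problems)) {
    stop("invalid association record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df$pos <- pos
  df$pvalue <- pval
  df$effect_allele <- toupper(df$effect_allele)
  rownames(df) <- NULL
  df[, c(SUMSTATS_COLUMNS[1:6], "trait_type", "study_id")]
}

#' Load a GWAS summary-statistics table
#'
#' Reads a tab-separated table with header columns
#' `rsid, chrom, pos, effect_allele, pvalue, trait, study_id`, validates
#' every row, and tags each record with the layer it came from. Row order
#' is preserved. Malformed rows abort with row-number diagnostics rather
#' than being silently dropped.
#'
#' @param path path to a TSV file.
#' @param trait_type `"microbe"` or `"metabolite"`.
#' @return A validated data.frame of association records.
#' @export
load_sumstats <- function(path, trait_type = c("microbe", "metabolite")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_sumstats(df, trait_type = trait_type)
}

#' Write association records to TSV
#'
#' @param df validated association data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(df, path) {
  out <- df
  if (is.numeric(out$pvalue)) out$pvalue <- format(out$pvalue, digits = 15)
  if (is.numeric(out$pos)) out$pos <- sprintf("%d", as.integer(out$pos))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain associations passing the suggestive-significance thresholds
#'
#' Keeps exactly the records whose p-value is strictly below the threshold
#' for their layer (`alpha_microbe` for microbe records, `alpha_metabolite`
#' for metabolite records). A p-value exactly equal to the threshold is
#' excluded. Input order is preserved.
#'
#' @param records validated association data.frame.
#' @param cfg a [threshold_config()].
#' @return The filtered data.frame (possibly zero rows).
#' @export
filter_significant <- function(records, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  if (nrow(records) == 0L) return(records)
  alpha <- ifelse(records$trait_type == "microbe",
                  cfg$alpha_microbe, cfg$alpha_metabolite)
  out <- records[records$pvalue < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse duplicate (rsid, trait) records to the smallest p-value
#'
#' Different source studies can report the same SNP-trait association; the
#' screen keeps one record per (rsid, trait) key, the one with the smallest
#' p-value. Output is sorted deterministically by (chrom, pos, rsid, trait).
#' A single rsid reported at two different positions is a data
#' inconsistency and raises an error naming the rsid.
#'
#' @param records validated association data.frame.
#' @return Deduplicated data.frame.
#' @export
dedupe_records <- function(records) {
  if (nrow(records) == 0L) return(records)
  pos_per_rsid <- tapply(records$pos, records$rsid,
                         function(p) length(unique(p)))
  conflicted <- names(pos_per_rsid)[pos_per_rsid > 1L]
  if (length(conflicted)) {
    stop("conflicting positions for rsid(s): ",
         paste(sort(conflicted), collapse = ", "), call. = FALSE)
  }
  key <- paste(records$rsid, records$trait, sep = "\r")
  ord <- order(records$pvalue)
  first <- !duplicated(key[ord])
  out <- records[ord[first], , drop = FALSE]
  out <- out[order(chrom_rank(out$chrom), out$pos, out$rsid, out$trait), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# numeric ordering of chromosome labels; X sorts after 22
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(chrom))
  r[chrom == "X"] <- 23L
  r
}
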