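#' Run the trio screen on in-memory objects
#'
#' The functional core of the pipeline:
#' dedupe -> threshold filter -> overlap join -> (optional locus merge) ->
#' gene annotation -> trio collapse -> allergy flagging. All stage counts
#' are recorded.
#'
#' @param microbe,metab validated association data.frames.
#' @param panel a [haplotype_panel()] (or `NULL`: exact matches only).
#' @param genes gene-model data.frame.
#' @param catalogs catalog data.frame or list of them.
#' @param overrides optional rsid-to-gene override map (see
#'   [annotate_loci()]).
#' @param thresholds a [threshold_config()].
#' @param ld an [ld_config()].
#' @param merge collapse loci tagging one region ([merge_loci()]); default
#'   `TRUE`.
#' @param dedupe collapse duplicate (rsid, trait) records to min-p before
#'   filtering; default `TRUE`.
#' @param allergy_terms term set for [flag_allergy_relevance()].
#' @param anchor nearest-gene anchor side (see [annotate_loci()]).
#' @return list with `trios` (flagged trio data.frame), `loci`, and
#'   `counts` (named stage counts).
#' @export
screen_trios <- function(microbe, metab, panel, genes, catalogs,
                         overrides = NULL,
                         thresholds = threshold_config(),
                         ld = ld_config(),
                         merge = TRUE, dedupe = TRUE,
                         allergy_terms = default_allergy_terms(),
                         anchor = "microbe") {
  counts <- c(microbe_in = nrow(microbe), metab_in = nrow(metab))
  if (dedupe) {
    microbe <- dedupe_records(microbe)
    metab <- dedupe_records(metab)
  }
  microbe_f <- filter_significant(microbe, thresholds)
  metab_f <- filter_significant(metab, thresholds)
  counts <- c(counts, microbe_filtered = nrow(microbe_f),
              metab_filtered = nrow(metab_f))

  loci <- find_overlaps(microbe_f, metab_f, panel, ld)
  validate_loci(loci, ld)
  counts <- c(counts, overlap_loci = nrow(loci))
  if (merge) {
    loci <- merge_loci(loci, panel, ld)
    counts <- c(counts, merged_loci = nrow(loci))
  }

  annotated <- annotate_loci(loci, genes, overrides, anchor = anchor)
  trios <- build_trios(annotated)
  trios <- flag_allergy_relevance(trios, catalogs, allergy_terms)
  counts <- c(counts, trios = nrow(trios),
              flagged = sum(trios$allergy_flag))
  list(trios = trios, loci = annotated, counts = counts)
}

#' Pipeline run configuration
#'
#' Bundles thresholds, LD parameters, and input/output paths. All
#' referenced input paths must exist at construction time.
#'
#' @param microbe,metabolite summary-statistics TSV paths.
#' @param panel reference-panel VCF path (`NULL` for exact-only mode).
#' @param genes gene-model file path (GTF or BED).
#' @param catalogs character vector of catalog TSV paths.
#' @param overrides optional rsid-to-gene override TSV path (columns rsid,
#'   gene).
#' @param out_dir output directory for the report and run summary.
#' @param thresholds a [threshold_config()].
#' @param ld an [ld_config()].
#' @param merge,dedupe,anchor see [screen_trios()].
#' @param seed integer recorded in the run summary (the screen itself is
#'   deterministic).
#' @return object of class `run_config`.
#' @export
run_config <- function(microbe, metabolite, panel = NULL, genes,
                       catalogs = character(0), overrides = NULL,
                       out_dir = ".",
                       thresholds = threshold_config(), ld = ld_config(),
                       merge = TRUE, dedupe = TRUE, anchor = "microbe",
                       seed = NULL) {
  paths <- c(microbe = microbe, metabolite = metabolite, genes = genes,
             panel = panel, overrides = overrides, catalogs)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths)) {
    stop("input path(s) not found: ",
         paste(missing_paths, collapse = ", "), call. = FALSE)
  }
  structure(
    list(microbe = microbe, metabolite = metabolite, panel = panel,
         genes = genes, catalogs = catalogs, overrides = overrides,
         out_dir = out_dir, thresholds = thresholds, ld = ld,
         merge = merge, dedupe = dedupe, anchor = anchor, seed = seed),
    class = "run_config"
  )
}

#' Run the full pipeline from files to a trio report
#'
#' Loads all inputs, runs [screen_trios()], and writes `trios.tsv` (the
#' report body; byte-identical across reruns with identical inputs) and
#' `run_summary.json` (stage counts, parameters, seed) under
#' `cfg$out_dir`. A run finding zero trios is still a successful run.
#'
#' @param cfg a [run_config()].
#' @return the [screen_trios()] result, invisibly, with `paths` added.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "load"
  res <- tryCatch({
    microbe <- load_sumstats(cfg$microbe, "microbe")
    metab <- load_sumstats(cfg$metabolite, "metabolite")
    panel <- if (!is.null(cfg$panel)) load_panel(cfg$panel) else NULL
    genes <- load_genes(cfg$genes)
    catalogs <- lapply(cfg$catalogs, load_catalog)
    overrides <- if (!is.null(cfg$overrides)) {
      utils::read.delim(cfg$overrides, header = TRUE, sep = "\t",
                        colClasses = "character")
    } else NULL
    stage <- "screen"
    screen_trios(microbe, metab, panel, genes, catalogs, overrides,
                 thresholds = cfg$thresholds, ld = cfg$ld,
                 merge = cfg$merge, dedupe = cfg$dedupe,
                 anchor = cfg$anchor)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(cfg$out_dir, "trios.tsv")
  trios_out <- res$trios
  for (col in c("microbe_p", "metab_p", "r2")) {
    trios_out[[col]] <- format(trios_out[[col]], digits = 10)
  }
  utils::write.table(trios_out, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_path <- file.path(cfg$out_dir, "run_summary.json")
  jsonlite::write_json(
    list(
      counts = as.list(res$counts),
      parameters = list(
        alpha_microbe = cfg$thresholds$alpha_microbe,
        alpha_metabolite = cfg$thresholds$alpha_metabolite,
        window_bp = cfg$ld$window_bp, r2_min = cfg$ld$r2_min,
        merge = cfg$merge, dedupe = cfg$dedupe, anchor = cfg$anchor
      ),
      seed = cfg$seed
    ),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  res$paths <- c(report = report_path, summary = summary_path)
  invisible(res)
}
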