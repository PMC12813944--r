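#' Default allergy/immune term set
#'
#' Terms matched (case-insensitive substring, after whitespace
#' normalization) against catalog trait strings to decide allergy
#' relevance: asthma, rhinitis, eczema, allergy, allergic disease, immune,
#' inflammation.
#'
#' @return character vector of terms.
#' @export
default_allergy_terms <- function() {
  c("asthma", "rhinitis", "eczema", "allergy", "allergic disease",
    "immune", "inflammation")
}

normalize_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Load a disease-link catalog
#'
#' A catalog is an offline TSV snapshot with columns
#' `entity, class, trait, provenance` mapping genes, microbes, or
#' metabolites to linked traits (emulating GWAS Catalog, gutMDisorder, and
#' HMDB style lookups). Lookups are case-insensitive after whitespace
#' normalization.
#'
#' @param path catalog TSV path.
#' @return data.frame with columns entity, class, trait, provenance.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("entity", "class", "trait")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("catalog missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$provenance)) df$provenance <- basename(path)
  bad <- !(df$class %in% c("gene", "microbe", "metabolite"))
  if (any(bad)) {
    stop("catalog entity class must be gene/microbe/metabolite; offending row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(trimws(df$entity)))) {
    stop("catalog with empty entity name", call. = FALSE)
  }
  df[, c("entity", "class", "trait", "provenance")]
}

#' Collapse annotated overlap loci into gene-microbe-metabolite trios
#'
#' Emits one trio per distinct (gene, microbe trait, metabolite trait) key.
#' When several loci share a key (e.g. different proxy pairs tagging one
#' region), the locus with the smallest product of the two p-values is
#' kept as the trio's supporting SNP pair. Output order is deterministic:
#' by (chrom, min supporting position, gene, microbe, metabolite).
#'
#' @param loci annotated loci from [annotate_loci()].
#' @return data.frame with columns gene, microbe, metabolite, microbe_snp,
#'   metab_snp, microbe_p, metab_p, chrom, mode, r2, gene_source.
#' @export
build_trios <- function(loci) {
  if (nrow(loci) == 0L) {
    return(data.frame(
      gene = character(0), microbe = character(0), metabolite = character(0),
      microbe_snp = character(0), metab_snp = character(0),
      microbe_p = numeric(0), metab_p = numeric(0), chrom = character(0),
      mode = character(0), r2 = numeric(0), gene_source = character(0),
      stringsAsFactors = FALSE
    ))
  }
  key <- paste(loci$gene, loci$microbe_trait, loci$metab_trait, sep = "\r")
  ord <- order(loci$microbe_p * loci$metab_p)
  pick <- ord[!duplicated(key[ord])]
  sel <- loci[pick, , drop = FALSE]
  out <- data.frame(
    gene = sel$gene,
    microbe = sel$microbe_trait,
    metabolite = sel$metab_trait,
    microbe_snp = sel$microbe_rsid,
    metab_snp = sel$metab_rsid,
    microbe_p = sel$microbe_p,
    metab_p = sel$metab_p,
    chrom = sel$chrom,
    mode = sel$mode,
    r2 = sel$r2,
    gene_source = sel$gene_source,
    stringsAsFactors = FALSE
  )
  min_pos <- pmin(sel$microbe_pos, sel$metab_pos)
  out <- out[order(chrom_rank(out$chrom), min_pos, out$gene,
                   out$microbe, out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag trios with catalogued immune/allergy links
#'
#' A trio is flagged when ANY of its three entities (gene symbol, microbe
#' taxon, metabolite name) appears in a catalog with a linked trait that
#' contains one of `allergy_terms` as a case-insensitive substring (after
#' whitespace normalization); `exact = TRUE` switches to whole-string
#' equality. All matching links are recorded with their entity class,
#' trait, and catalog provenance; the trio's `assigned_condition` is the
#' trait of its first matching link.
#'
#' @param trios data.frame from [build_trios()].
#' @param catalogs a single catalog data.frame or a list of them
#'   (from [load_catalog()]).
#' @param allergy_terms non-empty character vector of terms.
#' @param exact use exact trait matching instead of substring.
#' @return `trios` with added columns allergy_flag (logical),
#'   assigned_condition, disease_links (";"-separated
#'   `class:trait:provenance` strings).
#' @export
flag_allergy_relevance <- function(trios, catalogs,
                                   allergy_terms = default_allergy_terms(),
                                   exact = FALSE) {
  stopifnot(length(allergy_terms) > 0)
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  cat_all <- if (length(catalogs)) do.call(rbind, catalogs) else
    data.frame(entity = character(0), class = character(0),
               trait = character(0), provenance = character(0))
  cat_all$entity_norm <- normalize_term(cat_all$entity)
  cat_all$trait_norm <- normalize_term(cat_all$trait)
  terms <- normalize_term(allergy_terms)

  trait_matches <- function(trait_norm) {
    if (exact) trait_norm %in% terms
    else any(vapply(terms, function(t) grepl(t, trait_norm, fixed = TRUE),
                    logical(1)))
  }

  n <- nrow(trios)
  flag <- logical(n)
  links <- character(n)
  condition <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ent <- data.frame(
      name = normalize_term(c(trios$gene[i], trios$microbe[i],
                              trios$metabolite[i])),
      class = c("gene", "microbe", "metabolite"),
      stringsAsFactors = FALSE
    )
    hit_rows <- cat_all[cat_all$entity_norm %in% ent$name, , drop = FALSE]
    if (nrow(hit_rows)) {
      # entity name and class must both agree
      keep <- vapply(seq_len(nrow(hit_rows)), function(r) {
        any(ent$name == hit_rows$entity_norm[r] &
              ent$class == hit_rows$class[r])
      }, logical(1))
      hit_rows <- hit_rows[keep, , drop = FALSE]
    }
    if (nrow(hit_rows)) {
      ok <- vapply(hit_rows$trait_norm, trait_matches, logical(1))
      hit_rows <- hit_rows[ok, , drop = FALSE]
    }
    if (nrow(hit_rows)) {
      # deterministic regardless of catalog file order
      hit_rows <- hit_rows[order(match(hit_rows$class,
                                       c("gene", "microbe", "metabolite")),
                                 hit_rows$trait_norm, hit_rows$provenance), ,
                           drop = FALSE]
      flag[i] <- TRUE
      condition[i] <- hit_rows$trait[1]
      links[i] <- paste(sprintf("%s:%s:%s", hit_rows$class, hit_rows$trait,
                                hit_rows$provenance), collapse = ";")
    }
  }
  trios$allergy_flag <- flag
  trios$assigned_condition <- condition
  trios$disease_links <- links
  trios
}
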