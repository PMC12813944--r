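#' Paths to the packaged worked-example fixture
#'
#' The package ships a 12-trio worked example: paired microbe/metabolite
#' summary-statistics tables, a stub phased reference panel in which the
#' two lead SNPs of each trio are encoded in perfect LD, a gene-model GTF
#' with one protein-coding gene per trio, a mini disease-link catalog, and
#' a literature-override table. Genomic coordinates in the fixture are
#' synthetic (trio i sits on chromosome i): the source tables print rsIDs
#' and p-values but no positions, so positions and panel LD are stated by
#' construction, not measured from any real reference. See the fixture's
#' README for details.
#'
#' @return named list of file paths (microbe, metabolite, panel, genes,
#'   catalog, overrides).
#' @export
allergy_trios_fixture <- function() {
  dir <- system.file("extdata", "allergy-trios", package = "trioscan",
                     mustWork = TRUE)
  list(
    microbe = file.path(dir, "microbe.tsv"),
    metabolite = file.path(dir, "metabolite.tsv"),
    panel = file.path(dir, "panel.vcf"),
    genes = file.path(dir, "genes.gtf"),
    catalog = file.path(dir, "catalog.tsv"),
    overrides = file.path(dir, "overrides.tsv")
  )
}

#' Load the packaged worked-example fixture into memory
#'
#' @return list with microbe, metab, panel, genes, catalog, overrides.
#' @export
load_allergy_trios <- function() {
  fx <- allergy_trios_fixture()
  list(
    microbe = load_sumstats(fx$microbe, "microbe"),
    metab = load_sumstats(fx$metabolite, "metabolite"),
    panel = load_panel(fx$panel),
    genes = load_genes(fx$genes),
    catalog = load_catalog(fx$catalog),
    overrides = utils::read.delim(fx$overrides, header = TRUE, sep = "\t",
                                  colClasses = "character")
  )
}

#' Reference condition/function annotations for the worked example
#'
#' Free-text pass-through columns of the 12-trio example (assigned
#' condition group, gene function, SNP location labels) keyed by gene
#' symbol. These are carried, not computed.
#'
#' @return data.frame with columns gene, condition, gene_function,
#'   microbe_snp_location, metab_snp_location.
#' @export
allergy_trios_reference <- function() {
  dir <- system.file("extdata", "allergy-trios", package = "trioscan",
                     mustWork = TRUE)
  utils::read.delim(file.path(dir, "reference.tsv"), header = TRUE,
                    sep = "\t", colClasses = "character")
}
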