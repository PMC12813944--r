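#' Load gene models from GTF or BED
#'
#' GTF input (via rtracklayer) keeps `gene`-type features and reads the
#' `gene_name` and `gene_biotype` attributes; coordinates are 1-based
#' inclusive. BED input is a 6-column tab file `chrom, start, end, name,
#' biotype, strand` with half-open 0-based coordinates, converted to
#' 1-based inclusive on load. Biotypes other than `protein_coding` are
#' collapsed to `other`.
#'
#' @param path gene-model file (`.gtf`/`.gff` or `.bed`).
#' @param format override auto-detection: `"gtf"` or `"bed"`.
#' @return data.frame with columns name, chrom, start, end, biotype.
#' @export
load_genes <- function(path, format = NULL) {
  if (!file.exists(path)) stop("gene file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff", "gff2", "gff3")) "gtf" else "bed"
  }
  format <- match.arg(format, c("gtf", "bed"))
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    name <- gr$gene_name
    biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else
      rep("other", length(gr))
    genes <- data.frame(
      name = as.character(name),
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      biotype = as.character(biotype),
      stringsAsFactors = FALSE
    )
  } else {
    bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 5L) {
      stop("BED gene file needs >= 5 columns (chrom, start, end, name, biotype)",
           call. = FALSE)
    }
    genes <- data.frame(
      name = as.character(bed[[4]]),
      chrom = normalize_chrom(bed[[1]]),
      start = as.numeric(bed[[2]]) + 1,  # half-open 0-based -> 1-based inclusive
      end = as.numeric(bed[[3]]),
      biotype = as.character(bed[[5]]),
      stringsAsFactors = FALSE
    )
  }
  genes$biotype <- ifelse(genes$biotype == "protein_coding",
                          "protein_coding", "other")
  if (any(!nzchar(genes$name) | is.na(genes$name))) {
    stop("gene model with empty name", call. = FALSE)
  }
  if (any(genes$start > genes$end)) {
    stop("gene model with start > end", call. = FALSE)
  }
  rownames(genes) <- NULL
  genes
}

#' Nearest gene to a genomic position
#'
#' Distance to a gene body is 0 when the position lies within
#' \[start, end\], otherwise `min(|pos - start|, |pos - end|)`.
#' Protein-coding genes are searched first; an `other`-biotype gene is
#' returned only when the chromosome carries no protein-coding gene. Ties
#' are broken deterministically: smaller distance, then protein_coding
#' before other, then lexicographically smaller symbol.
#'
#' @param chrom chromosome label.
#' @param pos 1-based base-pair position.
#' @param genes gene-model data.frame from [load_genes()].
#' @return list with `gene` (one-row data.frame) and `distance_bp`, or
#'   `NULL` when the chromosome has no genes.
#' @export
nearest_gene <- function(chrom, pos, genes) {
  chrom <- normalize_chrom(chrom)
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  pc <- g[g$biotype == "protein_coding", , drop = FALSE]
  if (nrow(pc)) g <- pc
  inside <- pos >= g$start & pos <= g$end
  dist <- ifelse(inside, 0, pmin(abs(pos - g$start), abs(pos - g$end)))
  ord <- order(dist, g$biotype != "protein_coding", g$name)
  best <- ord[1]
  list(gene = g[best, , drop = FALSE], distance_bp = dist[best])
}

#' Assign a candidate gene to each overlap locus
#'
#' A literature override (rsid to gene symbol) wins when present for either
#' lead SNP, microbe side checked first; otherwise the nearest
#' protein-coding gene to the configured anchor position is used. The
#' annotation source (`override` or `nearest`) is recorded per locus. An
#' override naming a gene absent from the gene table is still applied as a
#' bare symbol, with a warning.
#'
#' @param loci data.frame from [find_overlaps()] (or [merge_loci()]).
#' @param genes gene-model data.frame from [load_genes()].
#' @param overrides named character vector mapping rsid to gene symbol, or
#'   a data.frame with columns rsid, gene; may be empty/`NULL`.
#' @param anchor which lead SNP anchors the nearest-gene lookup:
#'   `"microbe"` (default), `"metabolite"`, or `"midpoint"`.
#' @return `loci` with added columns gene, gene_distance_bp, gene_source.
#' @export
annotate_loci <- function(loci, genes, overrides = NULL,
                          anchor = c("microbe", "metabolite", "midpoint")) {
  anchor <- match.arg(anchor)
  if (is.data.frame(overrides)) {
    overrides <- stats::setNames(as.character(overrides$gene),
                                 overrides$rsid)
  }
  if (is.null(overrides)) overrides <- character(0)
  unknown <- setdiff(unname(overrides), genes$name)
  if (length(unknown)) {
    warning("override gene(s) absent from gene file: ",
            paste(sort(unique(unknown)), collapse = ", "), call. = FALSE)
  }

  n <- nrow(loci)
  gene <- rep(NA_character_, n)
  gdist <- rep(NA_real_, n)
  gsrc <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ov <- overrides[c(loci$microbe_rsid[i], loci$metab_rsid[i])]
    ov <- ov[!is.na(ov)]
    if (length(ov)) {
      gene[i] <- ov[[1]]
      gdist[i] <- NA_real_
      gsrc[i] <- "override"
      next
    }
    pos <- switch(anchor,
      microbe = loci$microbe_pos[i],
      metabolite = loci$metab_pos[i],
      midpoint = floor((loci$microbe_pos[i] + loci$metab_pos[i]) / 2)
    )
    hit <- nearest_gene(loci$chrom[i], pos, genes)
    if (is.null(hit)) {
      gsrc[i] <- "unannotated"
      next
    }
    gene[i] <- hit$gene$name
    gdist[i] <- hit$distance_bp
    gsrc[i] <- "nearest"
  }
  loci$gene <- gene
  loci$gene_distance_bp <- gdist
  loci$gene_source <- gsrc
  loci
}
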