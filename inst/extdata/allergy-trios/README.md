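# Packaged 12-trio worked example (synthetic coordinates)

Twelve gene-microbe-metabolite trios with their lead SNPs and published
p-values, encoded as pipeline inputs:

- `microbe.tsv` / `metabolite.tsv` — summary-statistics tables, one lead SNP
  per trio and layer. The rsIDs, trait names, and p-values are the printed
  values; **chromosome and position are synthetic** (trio *i* is placed on
  chromosome *i*, microbe SNP at 1,000,000 bp, metabolite SNP at
  1,060,000 bp), because the source tables print no coordinates.
- `panel.vcf` — a **stub reference panel** of 20 synthetic samples in which
  the two lead SNPs of each trio are encoded in perfect LD (identical phased
  haplotype columns, r² = 1). The true EUR r² values for these pairs are not
  printed anywhere, so the stub states the high-LD relationship by
  construction. It is labelled synthetic and must not be mistaken for
  1000 Genomes data.
- `genes.gtf` — one synthetic protein-coding gene model per trio, spanning
  both lead SNPs, carrying the published gene symbol.
- `catalog.tsv` — a mini offline disease-link catalog holding the published
  allergy/immune links (starred entities and their condition groups).
- `overrides.tsv` — a literature-override example (rs687289 -> ABO).
- `reference.tsv` — free-text pass-through columns (condition group, gene
  function, SNP location labels) keyed by gene symbol; carried, not
  computed.

Every file is plain text. Load the set with `trioscan::load_allergy_trios()` or get
paths with `trioscan::allergy_trios_fixture()`.
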