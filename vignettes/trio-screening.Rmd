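---
title: "Screening gene-microbe-metabolite trios from paired GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene-microbe-metabolite trios from paired GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscan)
```

## The screening model

Host genetic variants can be associated both with the abundance of a gut
microbial taxon (an mbQTL) and with the level of a blood metabolite (an
mQTL). When one locus carries both kinds of association, the shared genetics
suggests a gene-microbe-metabolite axis worth mechanistic follow-up —
for example in immune-mediated conditions such as asthma, rhinitis, and
eczema, where microbes, microbial metabolites, and host genes have each been
implicated separately.

trioscan implements this integration as a deterministic screen over
published summary statistics; no individual-level data, effect sizes, or
phenotype models are involved. The screen has five stages:

1. **Suggestive-significance filtering.** Keep microbe-layer associations
   with $p < \alpha_{mb}$ and metabolite-layer associations with
   $p < \alpha_{mt}$. Defaults are $\alpha_{mb} = 10^{-6}$ and
   $\alpha_{mt} = 10^{-5}$ — deliberately more lenient than genome-wide
   significance ($5\times10^{-8}$), because a pleiotropic locus need not
   reach the stringent level in both layers at once. The inequalities are
   strict: $p$ equal to the threshold is excluded.
2. **Overlap detection.** Two filtered records overlap when they share a
   lead SNP (exact rsID identity), or when their lead SNPs are LD proxies:
   same chromosome, separation at most $W$ base pairs (inclusive), and
   panel $r^2$ strictly greater than $\rho$. Defaults: $W = 250{,}000$,
   $\rho = 0.8$.
3. **Locus merging** (optional, on by default). Several SNP pairs can tag
   one signal; loci with the same trait pair whose lead SNPs are mutual
   proxies collapse to the pair with the smallest p-value product.
4. **Gene annotation.** Each locus gets the nearest protein-coding gene to
   its anchor SNP, unless a literature override maps the rsID to a symbol.
5. **Prioritization.** Trios are flagged when any of the three entities has
   a catalogued link to an immune/allergy trait.

## LD from phased haplotypes

For variants $A$ and $B$ with alternate-allele haplotype frequencies
$p_A, p_B$ and joint frequency $p_{AB}$,

$$r^2 = \frac{(p_{AB} - p_A p_B)^2}{p_A(1-p_A)\,p_B(1-p_B)},$$

which equals the squared Pearson correlation of the two 0/1 haplotype
columns. This is the classical haplotype-frequency measure; the reference
panel is read from a phased VCF (two haplotypes per diploid sample). For
unphased panels a clearly-labelled dosage mode computes the squared Pearson
correlation of 0/1/2 genotype dosages instead — a common fallback whose
value differs from haplotype $r^2$ when phase matters, which is why the
mode is recorded on the panel object rather than guessed.

Numerical choices worth knowing:

- A monomorphic variant leaves $r^2$ undefined (zero denominator). We raise
  an error rather than return 0, so undefined LD can neither create nor
  destroy proxies silently.
- Window semantics: $|pos_A - pos_B| \le W$ inclusive, on one chromosome.
  The $r^2$ comparison is strict ($> \rho$). Both choices are exercised at
  the exact boundary in the test suite (250,000 in; 250,001 out; $r^2$
  equal to the threshold out).
- Proxy lists are ordered by descending $r^2$, ties by ascending distance,
  then rsID — fully deterministic.
- Records whose rsID is absent from the panel are logged and skipped for
  proxy search but remain eligible for exact matches, since exact lead-SNP
  identity needs no LD evidence.

## Nearest-gene rule

Distance to a gene body is 0 inside $[start, end]$ and
$\min(|pos-start|, |pos-end|)$ outside. Protein-coding genes are preferred;
a non-coding gene is returned only when a chromosome carries no coding
gene. Ties break by distance, then biotype, then lexicographic symbol, so
annotation is invariant to gene-file row order. We deliberately compute
this distance directly rather than with interval-tree gap semantics
(where adjacent ranges have distance 0), which would disagree with the
definition above by one base pair.

Which SNP anchors the lookup for a proxy locus is genuinely open — the
microbe-side lead SNP is the default (the microbe layer is the rarer,
anchoring signal in this screen), with flags for metabolite-side or
midpoint anchoring.

## Duplicate handling

Two open design points were decided as follows:

- **Across studies**: the same SNP-trait association reported by several
  source studies collapses to the record with the smallest p-value
  (min-p dedupe, on by default, switchable off). A single rsID reported at
  two different positions is treated as a data inconsistency, not merged.
- **Within a region**: one anchor with several proxy partners emits one
  locus per partner; downstream, trios collapse per
  (gene, microbe, metabolite) key keeping the smallest p-product pair, and
  the optional mutual-proxy locus merge (on by default) removes redundant
  taggings before annotation.

## The synthetic world

The generator emulates exactly the statistical structure the screen
consumes, nothing more:

- **Panels**: within a block, variants are copies of a latent founder
  column, each entry flipped with probability $\varepsilon$; for a pairwise
  target $t$, $\varepsilon = (1 - t^{1/4})/2$ since the expected pairwise
  $r^2$ is $(1-2\varepsilon)^4$. Blocks with target 0 hold independent
  variants, so cross-block $r^2$ is finite-sample noise of order
  $1/n_{hap}$. Defaults: 200 haplotypes (100 diploid samples, the scale of
  a 1000-Genomes subpopulation), founder frequencies uniform on
  $[0.1, 0.9]$, high-LD target $0.96$.
- **Summary statistics**: planted loci draw the microbe p log-uniformly on
  $[10^{-14}, 10^{-7})$ and the metabolite p on $[10^{-14}, 10^{-6})$ —
  comfortably inside the thresholds, matching the order of magnitude of
  published mbQTL/mQTL hits. Each distractor violates exactly one pass
  condition, with margin: p drawn on $[2\times10^{-6}, 10^{-4}]$ (above
  $10^{-6}$ by at least 2x), or an independent SNP pair ($r^2 \approx
  1/200$, asserted $< 0.7$), or a high-LD pair placed 300 kb apart.
  Realized within-block $r^2$ is asserted $> 0.9$ for planted pairs at
  generation time, so finite-sample LD noise cannot flip any outcome.
- p-values are *planted, not computed from phenotypes*: the artifact
  implements the integration step, not the upstream GWAS. The block-flip
  model was chosen over coalescent simulation because it gives direct,
  testable control of pairwise $r^2$, which is the only panel property the
  screen consumes.

A green planted-recovery test therefore establishes that the screen's
filtering, windowing, LD, annotation, and flagging logic compose correctly
— it does **not** establish robustness to realistic human LD decay, allele
frequency spectra, rsID mismatches between studies and panel, population
mismatch, or p-value noise near the thresholds, none of which the stated
world contains.

## The packaged worked example

The 12-trio fixture encodes a published integrative result as pipeline
inputs. Its rsIDs, trait names, gene symbols, and p-values are the printed
values; its genomic coordinates are synthetic and its stub panel encodes
each trio's SNP pair in perfect LD, because true EUR $r^2$ values for those
pairs are not printed anywhere. The fixture demonstrates parsing,
filtering, exact/proxy overlap, annotation (including one literature
override, rs687289 → ABO), and flagging; it is not a re-derivation of the
original result from its 32 source GWAS. Condition assignments
("Asthma", "Eczema", ...) are carried in the fixture catalog, since the
assignment rule used to print them was not stated. (The source's Results
section mentions 19 metabolome datasets where its methods table lists 18;
we follow the table.)

```{r fixture}
fx <- load_allergy_trios()
res <- screen_trios(fx$microbe, fx$metab, fx$panel, fx$genes,
                    fx$catalog, fx$overrides)
res$counts
res$trios[1:3, c("gene", "microbe", "metabolite", "microbe_p", "metab_p",
                 "allergy_flag")]
```

## Known limitations

- P-values are taken at published face value: no genomic control,
  heterogeneity assessment, effect-size harmonization, or build liftover.
- Overlap is evidence of shared association, not colocalization; no
  posterior probabilities, conditional analysis, or Mendelian
  randomization are computed.
- Trait matching against catalogs is normalized substring matching, not
  ontology-aware mapping; `exact = TRUE` is available but equally naive.
- Chromosome X is treated as a single ordinary chromosome.
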