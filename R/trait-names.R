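# Packaged name pools for the synthetic-data generator. Plausible gut taxa
# and blood metabolites; purely cosmetic labels for simulated records.

#' Packaged gut-microbe taxon names for simulation
#' @return character vector.
#' @export
taxon_names <- function() {
  c(
    "Bifidobacterium bifidum", "Bifidobacterium angulatum",
    "Bifidobacterium longum", "Ruminococcus gnavus", "Dorea longicatena",
    "Eggerthella lenta", "Prevotella buccae", "Prevotella copri",
    "Megasphaera micronuciformis", "Bacteroides clarus",
    "Bacteroides uniformis", "Granulicatella adiacens",
    "Faecalibacterium prausnitzii", "Akkermansia muciniphila",
    "Roseburia intestinalis", "Blautia obeum", "Coprococcus comes",
    "Collinsella aerofaciens", "Alistipes putredinis",
    "Parabacteroides distasonis", "Eubacterium rectale",
    "Dialister invisus", "Streptococcus salivarius",
    "Veillonella parvula", "Lachnospira pectinoschiza",
    "Oscillibacter valericigenes", "Odoribacter splanchnicus",
    "Sutterella wadsworthensis", "Butyrivibrio crossotus",
    "Holdemanella biformis", "Anaerostipes hadrus",
    "Clostridium leptum", "Phascolarctobacterium faecium",
    "Desulfovibrio piger", "Methanobrevibacter smithii",
    "Fusicatenibacter saccharivorans", "Romboutsia ilealis",
    "Intestinimonas butyriciproducens", "Barnesiella intestinihominis",
    "Christensenella minuta"
  )
}

#' Packaged blood-metabolite names for simulation
#' @return character vector.
#' @export
metabolite_names <- function() {
  c(
    "Campesterol", "Succinylcarnitine", "4-Cholesten-3-one",
    "Octadecanedioate", "Octanoylcarnitine", "N-oleoyltaurine",
    "Isoeugenol sulfate", "3-Phenylpropionate", "Choline phosphate",
    "Lactosyl-N-behenoyl-sphingosine", "Glycosyl ceramide",
    "N-acetyl-aspartyl-glutamate", "Butyrate", "Propionate",
    "Indolepropionate", "Hippurate", "Taurocholate",
    "Glycochenodeoxycholate", "Trimethylamine N-oxide", "Kynurenine",
    "Serotonin", "p-Cresol sulfate", "Phenylacetylglutamine",
    "Sphingosine 1-phosphate", "Linoleoylcarnitine",
    "Deoxycarnitine", "Glutarylcarnitine", "Azelate",
    "Sebacate", "3-Indoxyl sulfate", "Cinnamoylglycine",
    "Catechol sulfate", "Imidazole propionate", "Urobilin",
    "Biliverdin", "Pyroglutamine", "N-acetylornithine",
    "Dimethylglycine", "Betaine", "Carnitine"
  )
}
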