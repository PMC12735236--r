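# isomalnet

Negative-mode LC–MS/MS dereplication and chemotyping of isomalabaricane
triterpenoids in marine sponge extracts.

Marine sponges of the genus *Rhabdastrella* produce isomalabaricanes — cytotoxic
triterpenoids with a trans-syn-trans 6,6,5-tricyclic core and a polyunsaturated,
variably oxidized side chain. Untargeted metabolomics of sponge extracts yields
hundreds of MS/MS features of which only a handful match authentic standards;
the rest must be annotated from their fragmentation chemistry. `isomalnet`
implements that computational chain as a tested, reusable R package:

1. **Formula/mass arithmetic** (`parse_formula`, `mz_deprotonated`, `rdbe`,
   `ppm_error`, `infer_delta_formula`): monoisotopic masses from IUPAC atomic
   masses, deprotonated-anion m/z including the electron mass
   (m/z[M−H]⁻ = M − m(H) + mₑ), ring-and-double-bond equivalents
   (RDBE = C − H/2 + N/2 + P/2 + 1), and bounded CHNOPS lattice search for the
   composition of an observed mass difference.
2. **Diagnostic neutral-loss annotation** (`detect_losses`, `classify`):
   a declarative rule engine over the fragmentation grammar of the compound
   class — side-chain acids lose CO₂ then CO₂+CH₄; 3-hydroxy-4-carboxy cores
   are dominated by the CO₂+H₂O loss and never lose CO₂+CH₄; acetates show an
   acetic-acid loss and fragment series offset by 44 Da; glycosides shed
   HexNAc/Hex Y-ions with the deprotonated HexNAc at m/z 202; nitrogenous
   congeners combine the anion nitrogen rule with a 57.02 Da (C₂H₃NO) loss;
   lyso-PI lipids print the 259/241/223 inositol-phosphate triad. Rules ship
   as editable JSON.
3. **Feature-based molecular networking** (`modified_cosine`, `build_network`):
   modified-cosine spectral similarity with precursor-shift peak matching
   (fragment tolerance 0.02 Da, parent tolerance 0.01 Da), edges above cosine
   0.7 with ≥ 5 matching peaks, mutual top-10 neighbour pruning, and molecular
   families capped at 100 nodes; GraphML export for Cytoscape-style viewing.
4. **Chemometrics** (`normalize_table`, `pca_table`, `hcluster`): sum-normalize
   → log₁₀ → auto-scale, then PCA (SVD with a fixed sign convention) and Ward
   hierarchical clustering for chemotype discovery.
5. **Synthetic corpus generator** (`generate_corpus`) and library
   identification (`match_library`), plus a `run_pipeline()` driver and a thin
   Rscript wrapper in `inst/scripts/isomal-pipeline.R`.

The package also ships the printed relative-content matrix of 16 authentic
isomalabaricane standards across nine sponge specimens (`table3_fixture()`),
the one piece of in-study data small enough to package.

## Worked example

```r
library(isomalnet)

## exact-mass arithmetic: the [M-H]- ion of a C30H40O4 triterpenoid
mz_deprotonated("C30H40O4")   # 463.2854
rdbe("C30H40O4")              # 11 degrees of unsaturation

## a seeded synthetic corpus: 42 features, 9 samples, two chemotypes
corpus <- generate_corpus(corpus_config(rng_seed = 1))
net <- build_network(corpus$spectra, network_params())
network_stats(net)
#> $n_nodes      42
#> $n_singletons 17
#> $component_sizes
#> 5 6 8
#> 1 2 1

## structural-class annotation of one spectrum
classify(corpus$spectra[[1]])$hypotheses[, c("class_id", "score")]
#>      class_id score
#> 1     SC_ACID   1.0
#> 2 ACETOXY_MOD   0.5

## chemometrics on the packaged standards table
hcluster(normalize_table(table3_fixture()), k = 2)$labels
#> PIBOC O34-077 ... PIBOC O63-136   -> cluster 1
#> PIBOC O66-089 O66-092 O66-109     -> cluster 2
```

The network statistics show the corpus features assembling into molecular
families of structurally related templates with the rest left as singletons;
the annotation ranks a side-chain carboxylic acid as the top hypothesis (the
0.5-score acetoxy hypothesis is the unavoidable shadow of the CO₂+CH₄ loss,
which is isomeric with an acetic-acid loss); and clustering the printed
standards table at k = 2 cleanly separates the three Phan Thiet specimens
(PIBOC O66-###) from the six others — the two chemotypes.

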