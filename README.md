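# whalescreen

Ligand-based virtual screening with WHALES 3D molecular descriptors, for
scaffold-hopping drug repurposing against the human dopamine transporter
(hDAT) — and, generally, for any multi-template 3D similarity screen.

Classical hDAT drugs bind the orthosteric (cocaine) site and carry
stimulant/addiction liability. Atypical inhibitors such as benztropine,
JHW007 and R/S-modafinil instead bind the S3 site in the intracellular
vestibule. This package implements the computational screen that finds
more of them: it turns molecules into charged, minimized 3D structures,
encodes each as a 33-value WHALES (Weighted Holistic Atom Localization
and Entity Shape) descriptor, and ranks a compound library by Euclidean
descriptor distance to a panel of query templates, so that hits share
shape and charge distribution with the queries without sharing their 2D
scaffold. Hit lists are then filtered by classical drug-likeness windows,
and a bookkeeping module recombines and validates MM/GBSA end-point
binding-energy component tables.

## The descriptor

For atoms with coordinates $x_i$ and Gasteiger–Marsili partial charges
$\delta_i$, each atom $j$ gets a charge-weighted covariance
$S_w(j) = \sum_i |\delta_i|(x_i-x_j)(x_i-x_j)^T / \sum_i |\delta_i|$,
defining the atom-centered Mahalanobis distance matrix
$\mathrm{ACM}(i,j) = \sqrt{(x_i-x_j)^T S_w(j)^{-1} (x_i-x_j)}$.
Per-atom isolation ($\min_{i\neq j}\mathrm{ACM}(i,j)$), remoteness
(mean) and their ratio IR are summarized by their 0–100th percentiles
(step 10), giving 3 × 11 = 33 values. Similarity between molecules x and
y is $D_{xy} = \sqrt{\sum_{j=1}^{33}(x_j-y_j)^2}$; smaller is more
similar. See `vignette("whales-screening")` for the conventions and
numerics.

## Installation and requirements

The package needs `obabel` (OpenBabel ≥ 3) and a `python` with RDKit on
the `PATH` (3D embedding, minimization and charging run through a
batched RDKit helper; format handling and 2D properties through
OpenBabel).

```r
# from the repository root
install.packages(".", repos = NULL, type = "source")
# run the test suite
testthat::test_dir("tests/testthat", package = "whalescreen",
                   load_package = "installed")
```

## Worked example

```r
library(whalescreen)

## four atypical-inhibitor query templates, prepared and described
templates <- default_templates()
tmol  <- prepare_collection(templates, seed = 7)
tdesc <- whales_descriptors(tmol)
round(tdesc[, c("isol_p000", "isol_p100", "rem_p050", "ir_p050")], 3)
#>             isol_p000 isol_p100 rem_p050 ir_p050
#> benztropine     0.179     0.656    1.733   0.273
#> JHW007          0.237     0.674    1.673   0.284
#> R-modafinil     0.197     0.805    1.706   0.299
#> S-modafinil     0.197     0.805    1.706   0.299

## a seeded synthetic library: decoys + planted analogs of the templates
lib <- generate_library(library_spec(n_decoys = 300,
                                     n_analogs_per_template = 2,
                                     seed = 11))
#> 308 molecules; 8 planted analogs
ldesc <- whales_descriptors(prepare_collection(lib, seed = 7))

## rank by nearest-template Euclidean distance
hits <- rank_library(tdesc, ldesc, top_k = 10)
head(hits[, c("molecule_id", "aggregate_distance", "rank")], 8)
#>       molecule_id aggregate_distance rank
#>  R-modafinil_an01         0.05119395    1
#>  S-modafinil_an01         0.05119503    2
#>  benztropine_an02         0.08373442    3
#>  benztropine_an01         0.14050727    4
#>          DEC00090         0.15098298    5
#>       JHW007_an01         0.15121777    6
#>  S-modafinil_an02         0.16732269    7
#>          DEC00212         0.17620270    8
```

The planted analogs dominate the top of the list — the screen retrieves
true 3D near-neighbors from a dissimilar background. Distances are
unitless descriptor-space distances; 0 means identical descriptors.

Drug-likeness of the three repurposed actives (the local anesthetics
mepivacaine, ropivacaine, bupivacaine):

```r
profile <- property_profile(active_compounds())
#>  molecule_id      mw   logp hba hbd  tpsa
#>  mepivacaine 246.348 2.7371   3   1 32.34
#>  ropivacaine 274.401 3.5173   3   1 32.34
#>  bupivacaine 288.428 3.9074   3   1 32.34
apply_windows(profile)$pass_all
#> TRUE TRUE TRUE   # all three inside MW/logP/HBA/HBD/TPSA windows
```

MM/GBSA component bookkeeping on the shipped six-complex hDAT table:

```r
report <- validate_component_table(hdat_gbsa_table())
report[4:5, ]
#>        system_id g_total claimed_total      residual   ok
#>   compound4-hDAT  -27.25        -27.25 -3.552714e-15 TRUE
#>  compound14-hDAT  -27.71        -27.71  2.842171e-14 TRUE
```

A thin command-line front end with the same verbs ships in
`exec/whales-screen` (`simulate`, `prepare`, `describe`, `screen`,
`filter`, `gbsa`).

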