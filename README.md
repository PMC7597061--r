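# lamp

Layered assessment on modules and pathways: network-based disease
classification in R.

`lamp` classifies diseases by the influence their genes exert on the rest
of a **directed** gene interaction network, rather than by the tissue or
organ a disease is named after. It is aimed at computational biologists
working with interaction databases (e.g. BioGRID bait–prey records) and
curated disease/pathway gene sets (e.g. KEGG DISEASE / KEGG PATHWAY):
diseases whose genes push on the same pathways end up in the same
category, whether or not they share a single gene.

## The model

Let the directed network's largest connected component (LCC) be
partitioned into topological modules `M_t` by the fast unfolding
(Louvain) algorithm, and let `F_layer_s^g` be layer `s` of the forward
BFS layered network rooted at gene `g` (layer index = shortest directed
path length), `R_layer_s^P` layer `s` of the reverse layered network
rooted at pathway `P`'s genes.

A disease `D` scores each module by the **inverse average layer
summation**

    IALS(D, M_t) = Σ_{g ∈ D ∩ M_t}  Σ_s |M_t ∩ F_layer_s^g|
                                    ─────────────────────────────
                                    Σ_s |M_t ∩ F_layer_s^g| · s

(sums over `s ≥ 1`), and each module scores a pathway by the **weighted
proportion summation**

    WPS(M_t, P) = Σ_{s ≥ 0}  |M_t ∩ R_layer_s^P| / |R_layer_s^P| · 2^(−s).

The impact score of a disease on a pathway is
`IS(D, P) = Σ_t IALS(D, M_t) · WPS(M_t, P)`; each disease's IS row is
min–max normalized to its **NIS** vector. Diseases whose genes lie
entirely in DOWN_LSCC — downstream of the network's strongly connected
core, so their perturbations cannot propagate back — are set aside as
category CATG-0. The remaining NIS vectors are clustered (Euclidean
distance, Ward.D2), the dendrogram is cut where the difference between
average between-category and within-category distance is largest, and
categories are characterized by Shannon entropy, cross-tabulation
against a reference classification, and Fisher over-representation of
overlapping-gene disease pairs. Driver nodes (structural
controllability via maximum bipartite matching), degree/betweenness
summaries and power-law exponents describe the network itself.

## Worked example

Every stage is runnable on seeded synthetic data with planted structure
(bow-tie roles, communities, disease groups), so nothing needs to be
downloaded:

```r
library(lamp)

spec  <- synthetic_spec(seed = 42)       # 4 planted disease groups
synth <- generate_network(spec)
sets  <- generate_gene_sets(synth)

lcc <- largest_weak_component(synth$network)
bt  <- bow_tie(lcc)
bt
#> <lamp_bowtie> LCC 122 = LSCC 96 + UP 10 + DOWN 12 + other 4

mods <- fast_unfolding(lcc, seed = 42)
mods
#> <lamp_modules> 5 modules over 122 genes, modularity 0.5467 (seed 42)

diseases <- restrict_gene_sets(sets$diseases, bt$lcc)
pathways <- restrict_gene_sets(sets$pathways, bt$lcc)
catg0    <- screen_catg0(diseases, bt)
catg0
#> <lamp_catg0> 4 CATG-0 diseases (12 pooled genes), 40 remaining

rest   <- subset_gene_sets(diseases, catg0$remaining_disease_ids)
scores <- impact_scores(lcc, rest, pathways, mods)

dm  <- distance_matrix(scores)
cut <- difference_vector_cut(ward_cluster(dm), dm)
cut$k
#> [1] 4

truth <- sets$truth$group[names(cut$labels)]
rand_index(cut$labels, truth)
#> [1] 1

assign <- make_category_assignment(cut$labels, catg0$catg0_disease_ids)
ora <- overlap_analysis(diseases, assign)
ora$table
#>                group with_overlap all_pairs
#> 1      same category          153       186
#> 2 different category           46       760
format(ora$fisher$p_value, digits = 3)
#> [1] "9.32e-100"
```

The bow-tie decomposition recovers the planted core/upstream/downstream
roles exactly; the difference-vector cut selects k = 4 categories, which
match the 4 planted disease groups perfectly (Rand index 1); and
overlapping-gene disease pairs are strongly over-represented within
categories (diseases drawn from the same block share genes), while 46
overlapping pairs still land in different categories — sharing a gene
does not force two diseases into the same class.

For real data, point `run_pipeline()` at an edge-list (or BioGRID tab
file), disease and pathway gene-set TSVs; it writes every stage's table
plus a JSON manifest. A thin command-line wrapper lives in
`inst/cli/lamp.R`.

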