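# phyloprof

Phylogenetic profiling asks whether the co-occurrence pattern of genes
across genomes carries functional information: genes (or gene families)
that are present and absent in the same set of species are hypothesised to
work in the same biological process. `phyloprof` implements a complete,
tested pipeline for putting that hypothesis to the test on enzyme/pathway
annotation data — from raw pairwise homology tables all the way to pathway
level statistics — together with a synthetic-data generator with planted,
tunable signal, so that every stage can be validated without any external
database.

The package is aimed at comparative genomicists and method developers who
want to (a) run an identical-profile enrichment screen over a pathway
annotation, (b) quantify how predictive profile similarity is for pathway
membership, co-expression or protein interaction, or (c) benchmark
profiling methodology under a controlled generative model.

## The statistics at the core

* **Gene objects.** Genes are clustered into *gene objects* — families or
  singletons — as connected components of a homology network whose edges
  require both a reported homology call and percent identity (relative to
  the shorter sequence) at or above a threshold (30% by default, 70% for
  the finer partition). Partitions are evaluated against EC-number labels
  with the Hubert–Arabie adjusted Rand index.
* **Profiles.** Each object gets a binary profile **P** over the ordered
  species set: bit *s* is 1 iff a member gene occurs in species *s*.
* **Identical-profile enrichment.** For a pathway with *n_f* member
  objects,

  F_pw = (# identical profile pairs among members) / (n_f (n_f − 1)/2)

  F_all extends the comparisons to the n_allO objects outside the pathway
  (outside–outside pairs are never compared):

  F_all = (# identical member pairs + # identical member–outside pairs) /
          (n_f (n_f − 1)/2 + n_f · n_allO)

  and the enrichment is E = F_pw / F_all. Significance comes from an
  empirical null — redraw n_f objects from the pool (10,000 draws by
  default), p = fraction of draws with E_r ≥ E — with Benjamini–Hochberg
  correction across pathways.
* **Pair similarity.** d_PP = |P₁ AND P₂| / |P₁ OR P₂| (Jaccard);
  pathway agreement A_PW = |PW₁ ∩ PW₂| / min(N₁, N₂) (overlap
  coefficient); their relationship is summarised by a least-squares
  logistic fit A_PW = 1/(1 + exp(−a·(d_PP − b))).
* **Prediction.** A self-contained bagged multi-label decision-tree
  ensemble (50 trees) predicts the two-level pathway hierarchy
  (class → map) from the profile bits, scored per label by out-of-bag
  area under the precision–recall curve and compared against
  occurrence-preserving label shuffles with a Wilcoxon rank-sum test.
* **Associations.** Expression is log-transformed, quantile-normalized and
  column-subsampled; pairwise Pearson r_GE is related to d_PP. Interacting
  protein pairs' d_PP distribution is compared with the non-interacting
  background by a Wilcoxon rank-sum test.

## Worked example

```r
library(phyloprof)

bundle    <- simulate_dataset(sim_config(pathway_coherence = 0.8, seed = 42))
partition <- build_families(bundle$homology, bundle$genes, min_identity = 30)
profiles  <- build_profiles(partition, bundle$genes, bundle$species,
                            kegg_annotated_only = TRUE)
nrow(profiles)                                   # 200 gene objects
nrow(group_identical_profiles(profiles)$groups)  # 163 unique profiles
evaluate_partition(partition, bundle$genes)      # ARI vs EC labels: 1

mem  <- pathway_memberships(bundle$genes, partition, bundle$definitions,
                            level = "map")
scan <- enrichment_scan(mem, profiles, n_draws = 1000, seed = 7)
head(as.data.frame(scan)[, c("pathway", "n_f", "f_pw", "f_all",
                             "enrichment", "p_empirical", "p_adjusted")], 5)
```

prints

```
  pathway n_f    f_pw   f_all enrichment p_empirical p_adjusted
1   M0101  12 0.06061 0.00732       8.28       0.007      0.252
2   M0404  10 0.04444 0.01080       4.12       0.039      0.468
3   M0202  17 0.00735 0.00216       3.41       0.030      0.468
4   M0109  11 0.05455 0.01406       3.88       0.061      0.549
5   M0406  10 0.02222 0.00668       3.32       0.087      0.626
```

Reading the top row: pathway `M0101` has 12 member objects, 6.1% of its
member pairs share an identical profile versus 0.73% when member profiles
are compared against the whole pool, an 8.3-fold enrichment; 7 of 1,000
random redraws of 12 objects reached that enrichment (raw p = 0.007),
which does not survive correction across the 50 tested pathways at this
simulation size (adjusted p = 0.25). The family clustering itself is
perfect here (adjusted Rand index 1 against the planted EC labels) because
the simulated within-family identities all exceed the 30% threshold.

A command-line front end covers the common stages:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "phyloprof.R", package = "phyloprof"))')
Rscript $CLI simulate --seed 3 --out sim/
Rscript $CLI families --species sim/species.tsv --annotation sim/annotation.tsv \
        --homology sim/homology.tsv --pathways sim/pathways.tsv \
        --min-identity 30 --high-confidence-only --out families.tsv
Rscript $CLI enrich --species sim/species.tsv --annotation sim/annotation.tsv \
        --homology sim/homology.tsv --pathways sim/pathways.tsv \
        --families families.tsv --draws 10000 --out enrichment.tsv
```

`run_config()` + `run_all()` drive the full pipeline (families → profiles
→ surveys → enrichment → pair similarity → prediction → associations) from
one configuration with per-stage derived seeds and an md5-checksummed run
manifest; reruns are byte-identical.

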