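---
title: "Methods and design notes for phyloprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for phyloprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phyloprof)
```

This vignette explains the models and statistics the package implements,
the tunable parameters that matter, what the synthetic-data generator does
and does not emulate, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. From homology edges to gene objects

The unit of analysis is the *gene object*: a gene family or a singleton
gene. Objects are connected components of a homology network in which an
edge between two genes is retained iff

1. a pairwise homology relation is reported for them (the edge exists in
   the input table),
2. its percent identity — defined relative to the shorter of the two
   sequences — is at or above `min_identity`, and
3. optionally, its confidence grade is `high`.

The identity comparison is inclusive (`>=`): the sources that grade
homology calls do not specify strictness, and an inclusive boundary is the
convention that keeps a reported "30%" edge in a 30% network. Orthologous
and paralogous edges are treated identically throughout. Genes present in
the annotation but absent from the retained network become singleton
objects. Raising the threshold can only remove edges, so the partition at
a higher threshold refines the partition at a lower one — a property the
suite asserts on every simulated bundle.

Duplicate homology rows (the same unordered pair listed twice) are
collapsed keeping the maximum identity, with `high` confidence winning
over `low`. This is conservative *toward* family merging and, more
importantly, deterministic and order-independent.

Partition quality is measured against enzyme function with the
Hubert–Arabie adjusted Rand index, treating each gene's *set* of EC
numbers as its function label (identical sets, identical label; the empty
set is its own label `"none"`). Unlabelled genes are included by default
under that shared label; a switch excludes them. The implementation is
checked against an independent pair-counting oracle,
`2(N00·N11 − N01·N10) / ((N00+N01)(N01+N11) + (N00+N10)(N10+N11))`.

## 2. Profiles and identical-profile enrichment

A profile is a binary vector over the *ordered* species set: multiplicity
is ignored, a single member gene in a species sets the bit. Two profiles
are the same only when every bit agrees — the deliberate all-or-nothing
criterion of the approach; no mismatch-tolerant grouping is offered.

For a pathway with `n_f` member objects, `F_pw` is the fraction of
identical pairs among all `n_f(n_f−1)/2` member pairs, and `F_all` adds
the `n_f · n_allO` member-versus-outside comparisons to the denominator
(outside–outside pairs are never compared, so `F_all` measures how special
the members' profiles are relative to the pool, not the pool's own
redundancy). `E = F_pw / F_all`.

Pathways with `n_f < 2` have no within-pair, so `F_pw` — and everything
downstream — is *undefined*, never zero. They are reported, flagged
untestable and excluded from the multiple-testing family (their inclusion
is a config switch; excluding non-tests from the Benjamini–Hochberg family
is the defensible default).

The null redraws `n_f` objects uniformly without replacement from the full
object pool — sampling objects, not genes, so profile multiplicities are
preserved — and recomputes `E_r` against the complementary outside set.
`p` is the plain fraction of draws with `E_r ≥ E`; when zero draws reach
the observed value the report shows `1/n_draws` with a floored flag,
avoiding a literal zero. Draws with undefined `E_r` (`F_all = 0`) count as
non-exceeding, a conservative choice whenever the observed `E` is defined.
Each pathway derives its own RNG seed from the root seed and the pathway
id (a stable string hash), so single-pathway results are reproducible
regardless of scan order or scan composition.

## 3. Pair similarity, pathway agreement and the logistic link

`d_PP` is the Jaccard index of the presence bits. Pathway agreement uses
the printed overlap-coefficient form `|PW₁ ∩ PW₂| / min(N₁, N₂)`: it
saturates at 1 whenever one pathway list contains the other, which a true
Jaccard does not; both forms are available (`method = "jaccard"`).
Pairs in which either object lacks pathway annotation have undefined
agreement and are excluded from fits.

Pair sampling draws unordered distinct pairs uniformly *with replacement
across draws*: at the intended scale (10⁵ draws from millions of pairs)
collisions are immaterial, and with-replacement keeps every draw
exchangeable.

The logistic fit `y = 1/(1 + exp(−a(x − b)))` is least squares with a
multi-start grid (`a ∈ ±{1,5,20}`, `b ∈ {0.25,0.5,0.75}`) because a
single-start fit of this curve is fragile. Two degeneracies are flagged
rather than reported: constant input (no spread in `x` or `y`) and the
*flat-fit ridge* — on trendless data any near-constant curve fits equally
well, so the optimizer lands somewhere on the ridge `a·(x−b) ≈ const`
with arbitrary, meaningless parameters. The fit is declared
non-informative when the best curve varies by less than 0.01 over the
observed `x` range. When parameters are reported, an optional bootstrap
standard error of the slope supports the "is the slope distinguishable
from zero" question.

## 4. Hierarchical multi-label prediction

The published analysis used an external hierarchical multi-label
classifier in random-forest mode. We implement an equivalent,
self-contained method rather than emulating that tool bit for bit — its
"Jaccard-distance metrics" configuration has no unambiguous public
semantics, so distance-based splitting is not imitated:

* bagged ensemble (default 50 trees) of multi-label decision trees over
  the binary profile features;
* split criterion: mean per-label Gini reduction, computed for all
  features at once via one cross-product per node; ties go to the
  lowest-index feature for determinism;
* leaves predict per-label frequencies; an object's score for a label is
  the mean over the trees in which the object was out-of-bag;
* the class/map hierarchy is enforced afterwards by lifting each class
  score to the maximum of its child map scores, so no map outranks its
  parent.

Per-label performance is the area under the precision–recall curve with a
step-wise convention: one point per distinct score (ties share a
threshold), area = Σ precision·Δrecall, with the recall-0 anchor at the
first threshold's precision. No linear interpolation between PR points —
trapezoidal interpolation is known to be optimistic. A constant score
yields exactly the label prevalence. The implementation is verified
against an exhaustive threshold-sweep oracle on all small inputs.

Note a property of this (standard) convention that matters when reading
null results: under a random but *tied* ranking — which out-of-bag tree
scores are — the expected AUCPRC exceeds the prevalence slightly
(≈ +0.05 at 200 objects and 10 labels in the suite's null world), because
precision and Δrecall are positively correlated within tie groups. The
null-calibration test therefore checks each label's AUCPRC against its
prevalence *within two across-run standard errors*, which brackets this
small-sample optimism; it does not assert exact equality.

Label shuffles preserve each label's occurrence count exactly and never
assign the same label twice to one object (each label's tokens are dealt
to distinct objects without replacement). True per-label AUCPRCs are
compared to run-averaged shuffled ones by a two-sided Wilcoxon rank-sum
test.

## 5. Expression and interaction associations

Expression preprocessing is natural-log transform (the log base is
unspecified in the source conventions; natural log is the package's
choice), quantile normalization, then Bernoulli column subsampling
(default keep probability 0.10, the usual shortcut for very large
hybridization collections). Quantile normalization replaces each sample's
rank-r value by the across-sample mean of rank-r values, ties receiving
the mean of their rank slots; rank slots that are already constant across
samples are passed through bit-exactly, which makes the operation
idempotent to the bit on tie-free data.

Co-expression analysis takes all pairs of a random gene subset (default
500) having both a profile (through their object) and an expression row,
and reports the d_PP–r_GE Pearson correlation, a linear fit, a logistic
fit and median r_GE per 0.1-wide d_PP bin. Two genes of the *same* object
get d_PP = 1 and are retained by default (a switch drops them) — the
annotation cannot distinguish them functionally, and dropping them is a
filtering decision, not a similarity statement.

The interaction screen keeps experimentally supported pairs, maps both
endpoints to profiled objects and compares their d_PP distribution with
the exhaustive non-interacting background (all mapped pairs not reported
interacting; uniformly subsampled with a recorded seed above 10⁶ pairs)
using a two-sided Wilcoxon rank-sum test.

## 6. The synthetic-data generator: what it emulates, and what not

`sim_config()` describes a scaled-down enzyme-annotation snapshot.
Defaults (fixed up front, with the reasoning below, and not revisited):

| parameter | default | why |
|---|---|---|
| `n_species` / `n_kegg_species` | 39 / 24 | the canonical species-panel split of the motivating data |
| `n_families` + `n_singletons` | 180 + 20 | a 200-object pool: large enough for permutation structure, small enough for seconds-scale tests |
| `n_classes` × `maps_per_class` | 5 × 10 | 50 pathways, two-level hierarchy |
| maps per object | 1 + min(2, Poisson(1.2)) | 1–3 maps, mean ≈ 2, the multi-annotation regime of pathway databases |
| `presence_prob` | 0.6 | typical per-species presence of a conserved enzyme family |
| `pathway_coherence` (ρ) | 0.5 | half the pathways carry planted signal |
| `profile_flip_noise` (ε) | 0.05 | mild annotation noise |
| `archetype_reuse_decay` | 0.8 | see below |
| identities within / decoy | U(60,95) / U(5,25) | within-family identity above, decoys below, the 30% threshold, so the default world is exactly recoverable |
| `block_correlation` | 0.7 | strong but noisy co-expression blocks |
| `ppi_beta` | 6 | interaction odds rise ~e⁶ across the d_PP range |

**Profile model.** Pathway archetypes are independent Bernoulli(π) bit
vectors (redrawn until non-zero). Objects whose home pathway is coherent
realise that archetype with per-bit flip probability ε. All other family
objects *copy an archetype drawn from the pathway pool with geometrically
decaying weights* — a deliberate deviation from fully independent
background profiles. Real snapshots reuse profiles heavily (hundreds of
objects can share the all-present profile; a large fraction of objects
share their profile with at least one other object), and identical-profile
statistics are only non-degenerate when collisions occur: with independent
39-bit profiles two objects collide with probability ~10⁻¹¹, every
`F_pw` would be zero and every permutation p-value exactly 1. The decay
0.8 keeps the expected number of identical member pairs per pathway in the
same regime as the real data's map-level memberships (~2–3), the quantity
that drives the enrichment statistic. Singleton objects carry one gene and
therefore a single-species profile, exactly as in the real pipeline.

The generator does **not** evolve gain/loss on a phylogeny — no analysis
downstream uses tree structure, only the profile matrix — and simulates
identity values rather than sequences. Consequently a green test
establishes that the *statistics behave correctly given profiles with the
stated collision structure*; it says nothing about phylogenetic realism of
the profiles themselves, nor about upstream alignment/identity estimation.

**Exactness worlds.** Two properties are only exactly derivable in
restricted configurations, and are tested there: "ρ=1, ε=0 ⟹ F_pw = 1
for every pathway" needs one map per object and no singletons (extra maps
import foreign archetypes into a pathway's member set; singleton profiles
are single-bit), and exact family recovery (ARI = 1) needs all
within-family identities above the threshold and no decoy edges above it.

## 7. Acceptance-test worlds: two calibration notes

**Null calibration (left red).** The acceptance criterion asks for
near-uniform permutation p-values (Kolmogorov–Smirnov < 0.15) on a
ρ = 0 world with 50 pathways and 200 objects. With 1–3 maps per object —
the generator's own contract — memberships are n_f ≈ 5–9, and with the
realistic collision regime above, roughly a fifth of pathways observe
*zero* identical member pairs. For them `E = 0` and every null draw ties
or exceeds, so `p = 1` exactly: a point mass that alone forces KS ≥ 0.2
(measured 0.22–0.33 across seeds). The p-values are *valid* — the
companion bound, fraction of p ≤ 0.05 within [0.01, 0.12], holds — just
discrete and super-uniform, as empirical permutation p-values of a
sparse discrete statistic are. Meeting the KS bound would require either
every object to carry the maximum three maps or a collapse of the profile
repertoire to a handful of profiles; both distort the stated world, so the
assertion is left red rather than engineered green.

**Planted-signal recovery.** Under flip noise, only exact archetype
copies contribute identical pairs; a copy survives ε-flipping with
probability u = (1−ε)^n_species — 0.135 at 39 species but 0.54 at 12.
Since the criterion fixes ε = 0.05 and n_f ≥ 10 but not the species
count, the test world uses 12 species and ~12 home families per map,
giving ≥ ~5 expected surviving copies per pathway, which separates
cleanly from the permutation null. This is the honest way to keep the
all-or-nothing identity criterion testable under noise — its exponential
signal decay with species count is a real property of the method, not of
the implementation.

## 8. Numerical and reproducibility choices

* All RNG is localized: routines snapshot and restore `.Random.seed`, so
  calling package functions never perturbs a user's RNG stream.
* Stage seeds derive from one root seed by a stable string hash of the
  stage/pathway name (kept below 2³¹), making every stage independently
  reproducible.
* Species-tree agglomeration (complete linkage, Euclidean distance on
  profile columns) breaks merge ties toward the lowest index pair;
  heights are reported as merge heights in the Newick output.
* Result writers serialise floats at 6 significant digits and sort rows
  by id; run manifests record an md5 checksum per output, and reruns with
  identical config are byte-identical.

## 9. Known limitations

* The enrichment null assumes exchangeability of objects across pathways;
  it does not condition on pathway composition biases (e.g. species
  coverage of members).
* The prediction ensemble is an equivalent of, not a replica of, the
  published classifier; absolute AUCPRC values are not comparable across
  implementations, which is why all assessments are relative to
  occurrence-preserving shuffles.
* The overlap-coefficient agreement saturates for nested pathway sets;
  interpretation of A_PW = 1 is "containment", not "identity".
* With many species and realistic noise, exact-identity statistics lose
  power exponentially; analyses of deep species panels should treat
  negative enrichment results with corresponding caution.
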