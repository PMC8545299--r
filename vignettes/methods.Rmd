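---
title: "Splitting protein functional families with embedding-space clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting protein functional families with embedding-space clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funsplit)
```

## The problem

Functional families such as CATH FunFams group protein domains that are
assumed to share a molecular function. In practice some families are
*impure*: their members carry different Enzyme Commission (EC) annotations,
either because the family genuinely mixes functions or because
multifunctional enzymes and missing annotations blur the picture. funsplit
re-clusters each family in the space of fixed-length protein language-model
embeddings (e.g. 128-dimensional contrastively tuned transformer
representations), where functional relatedness is often better resolved
than in sequence-identity space, and asks whether the resulting sub-clusters
are functionally more consistent than the family itself.

## The procedure

For proteins $x, y$ with embeddings in $\mathbb{R}^D$ the package supports
Euclidean distance $d(x,y) = \sqrt{\sum_i (x_i-y_i)^2}$ (the default),
Manhattan distance $\sum_i |x_i-y_i|$, and cosine distance
$1 - \frac{x\cdot y}{\lVert x\rVert\,\lVert y\rVert}$. Cosine is offered for
completeness: within a family most embedding pairs share orientation, so
cosine distances collapse towards zero and carry little signal.

**Threshold selection.** DBSCAN needs a closeness threshold $\theta$.
Families differ too much for a single global value, while a per-family
$\theta$ would be contaminated by exactly the impurity we want to detect —
a wide family may be wide *because* it is impure. The compromise is a
superfamily-level value: for every member of every family we compute its
average distance to its family co-members, pool these averages over all
families of the superfamily (each member counted once, singleton families
skipped), and take a quantile — by default the median, so half of a
superfamily's sequences are on average within $\theta$ of their co-members.
Quantiles use linear interpolation between order statistics (the
`type = 7` convention); the choice is recorded in the threshold table so
runs are reproducible. Quantiles 0.25 and 0.75 give a stricter and looser
variant: smaller $\theta$ yields more, smaller, seemingly purer clusters.

**Clustering.** Within each family, DBSCAN is run on the distance matrix
with neighborhood size $n$ (default 5, counting the point itself). A point
is *core* when at least $n$ points lie strictly within $\theta$ of it —
the strict inequality follows the closeness definition $d(A,B) < \theta$;
reference implementations typically use $\le$, a difference visible only on
exact ties. Clusters are connected components of mutually reachable core
points plus border points; everything else is an outlier. Two conventions
make results deterministic: members are processed in ascending input order,
and a border point reachable from several clusters joins the
first-discovered one. $n$ may also be given as a fraction $x$ of the family
size, resolved as $\max(2, \mathrm{round}(x\,|F|))$ with half-away-from-zero
rounding; $n = 1$ would make every point core, hence the floor of 2.

**Purity.** Only EC numbers specified to all four levels count as
annotations; partial labels are treated as absent. A cluster is *pure* when
all of its annotated members carry *identical* annotation sets: a cluster
whose members all share the same two EC numbers is pure (a multifunctional
sub-family), while one member annotated EC1+EC2 next to a member annotated
EC1 alone makes the cluster impure — deliberately conservative, since the
lone EC1 may simply be incomplete. For a family $F$,

$$\mathrm{Purity}(F) = 100 \cdot
  \frac{\#\text{pure clusters}}{\#\text{clusters with ECs}},$$

and the sequence-weighted analogue replaces cluster counts by the number of
sequences in those clusters (un-annotated members of an annotated cluster
count through their membership). Outliers enter neither statistic; their
share of the family is reported separately. Families with no annotated
cluster have undefined purity and are excluded from summaries. The
arithmetic never looks inside a label, so any labelling — ligand codes,
phenotypes — can stand in for EC numbers.

**Guarding against over-splitting.** Splitting a family into $N$ singletons
makes every cluster trivially pure, so purity alone is gameable. Two
safeguards are computed. First, the *random null*: a partition with exactly
the observed cluster-size multiset and outlier count but uniformly random
membership (`simulate()` on a fit); an informative clustering must beat its
own null by a wide margin. Second, the *EC-spread diagnostic*: for each EC
number, the number of clusters in which it occurs — ideally one; optionally
outliers count as singleton clusters, which makes the diagnostic stricter.

**Uncertainty.** All dataset-level summaries carry percentile bootstrap
confidence intervals (default 1000 resamples, 95% level, equal tail
probabilities), resampling families. Sequence-weighted statistics are also
bootstrapped over families, keeping each family's proteins together;
resampling proteins instead would break within-family dependence. Every
bootstrap and every null draw is seeded, and seeds are derived from one
per-call seed by fixed offsets so each interval is independently
reproducible without touching the caller's RNG stream.

## Dataset filters

The pre-clustering filters mirror how evaluation datasets of this kind are
assembled, and always apply in a fixed order — member-level removals first,
then orphan removal, then superfamily selection — so that, for example, a
two-member family loses a multi-segment protein *before* the orphan rule
sees the survivor. Available switches: dropping multi-segment proteins
(their embeddings are unreliable), dropping orphan families, keeping only
superfamilies with at least one impure family, keeping only labels with
experimental evidence (`ECO:0000269`), and keeping only families consisting
entirely of single-domain proteins. Multi-segment and single-domain status
are consumed as boolean flag columns of the annotation table; the package
does not derive them from structure data. The filter set is idempotent.
Thresholds are always computed from *all* families of a superfamily,
including un-annotated ones; by default only families with at least one
annotated member are then clustered.

## The synthetic generator

`simulate_families()` builds the geometry the method assumes: superfamilies
of families, each family a mixture of well-separated isotropic Gaussian
components, each component tied to one synthetic four-level EC set drawn
from disjoint blocks per superfamily. Its defaults are the reference
conditions used throughout the tests: 2 superfamilies x 4 families x 2
components x 10 members in 128 dimensions, separation 20 at spread 1, 10%
multifunctional components (two ECs, identical on all members — a *pure*
multifunctional group), 10% withheld annotations, 5% isolated noise points.

Two geometric choices matter. First, `within_component_spread` is defined
as the *expected distance between two members of a component* (per-
coordinate standard deviation $\mathrm{spread}/\sqrt{2D}$), not the raw
coordinate noise; otherwise a component's diameter would grow with
$\sqrt{D}$ and the separation/spread hardness knob would mean different
things at different dimensions. Second, component centers are drawn on a
sphere of radius equal to the separation and re-drawn until all pairwise
center gaps are at least 1.3x the separation: random directions in high
dimension are nearly orthogonal (typical gap $\sqrt{2}\times$ radius), and
the rejection step keeps the *minimum* gap comparable to the typical one,
so a single separation number controls hardness rather than the luck of
one close pair. Noise points sit at radius 4x separation, guaranteeing at
least 3x separation from every center, and are left un-annotated.

What the generator does *not* emulate: the anisotropic, heavy-tailed
geometry of real language-model embeddings, family-size skew, correlated
annotation errors, and the sequence-space structure that makes the 1-PIDE
baseline meaningful. Passing the planted-recovery tests therefore shows the
machinery is correct, not that real families will split as cleanly.

## Numerical and degenerate-input choices

Distance matrices are computed in double precision and symmetrized by
construction (upper triangle mirrored), so downstream symmetry checks use a
$10^{-9}$ tolerance only as a guard. Cosine similarities are clipped at 1
before conversion to distance to absorb rounding undershoot. A percent-
identity matrix is accepted on either the fraction or the 0-100 scale,
detected from its diagonal, and rejected if entries leave $[0,1]$ after
rescaling. Singleton families cannot contribute to thresholds and cluster
to a single outlier; a superfamily of only singletons has no threshold and
its families are skipped with a logged reason. Two identical members give
the degenerate threshold $\theta = 0$, reported with a warning. `n` larger
than the family size is a warning, not an error — every member then becomes
an outlier, which is a legitimate outcome.

## Problem sizes in the tests

The test-suite simulations are sized for quick iteration: recovery checks
use 1 superfamily x 3 families x 2 components x 8 members in 32 dimensions
over 20 seeds; the reference-implementation comparison uses 200 random
instances of up to 64 points; bootstrap coverage uses 500 replicate
experiments of 200 observations; the random-null uniformity check uses
2000 seeded draws on a 6-member family. The acceptance script runs the
generator at its defaults and recomputes every reported number at run time.

## Limitations

Purity can only be evaluated where annotations exist, and annotation gaps
themselves create apparent impurity; the conservative set-identity rule
counts some incomplete annotations as impure. The method inherits DBSCAN's
sensitivity to $\theta$: quartile variants bracket, but do not remove, that
dependence. Embeddings are consumed as input — nothing here runs a language
model — and the PIDE helper's alignment convention is one of several
reasonable choices, so sequence-distance results depend on how identities
were computed.
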