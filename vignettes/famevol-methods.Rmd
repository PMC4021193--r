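---
title: "Models and methods behind famevol"
author: "famevol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
```

famevol re-implements, as one tested toolbox, the analysis chain commonly
applied to plant gene superfamilies such as the soybean expansins: identify
the family from domain evidence, classify it phylogenetically, reconstruct
its duplication history and date it, and ask how selection and function
diverged among subfamilies afterwards. This vignette explains the models,
the tunable parameters, and the choices made where the methods literature
leaves the design open.

## The codon substitution model

The core engine is a GY94-style Markov model on the 61 sense codons of the
standard genetic code. The instantaneous rate from codon $i$ to $j$ is zero
unless the codons differ at exactly one position, and otherwise

$$q_{ij} = \pi_j \,\kappa^{\mathbb{1}[\text{transition}]}\,
  \omega^{\mathbb{1}[\text{nonsynonymous}]},$$

with stationary codon frequencies $\pi$ (equal or F3x4, the default),
transition/transversion ratio $\kappa > 0$, and
nonsynonymous/synonymous ratio $\omega \ge 0$ — the object of inference:
$\omega < 1$ indicates purifying selection, $\omega > 1$ positive
selection. The matrix is reversible, so transition probabilities are
computed by a symmetric eigendecomposition, and likelihoods by Felsenstein
pruning with per-column pattern compression and underflow rescaling.

Site-to-site variation in $\omega$ is modelled as a finite mixture of
classes sharing $\kappa$ and branch lengths:

* **M0** — one ratio for all sites (1 $\omega$-parameter);
* **M3** — three discrete classes, free proportions and ratios (5);
* **M7** — $\omega \sim \mathrm{Beta}(p, q)$ on $(0,1)$, discretized into
  10 equal-probability categories at their slice medians (2);
* **M8** — the beta component with weight $p_0$ plus one extra class at
  $\omega_s \ge 1$ (4);
* **branch-site model A** — classes 0, 1, 2a, 2b: $\omega_0$ and 1 on
  background branches, with classes 2a/2b switching to a shared
  $\omega_2 \ge 1$ on designated foreground branches, split in proportion
  $p_0 : p_1$. The null for the foreground test fixes $\omega_2 = 1$.

**Rate scaling.** All class matrices share one scale factor chosen so the
proportion-weighted mean *background* substitution rate is 1; branch
lengths are therefore expected substitutions per codon averaged over site
classes. The simulator uses the identical convention, so simulation and
inference are exact inverses.

**Optimization.** Parameters are transformed to unconstrained scales
(logs, logits, softmax for proportions) and maximized with `nlminb`
(relative tolerance $10^{-10}$, multiple starts). Two structural choices
keep the nested-model dominance guarantees sharp: M3 and M8 always include
a warm start loaded from an internally fitted M0 / M7 solution, so
$\ell(\mathrm{M3}) \ge \ell(\mathrm{M0})$ and
$\ell(\mathrm{M8}) \ge \ell(\mathrm{M7})$ hold to optimizer tolerance; and
the branch-site fits estimate $\kappa$ and the branch-length scale once
under M0 and hold them fixed for null and alternative, which removes most
of the cost of the repeated fits without biasing the likelihood-ratio
statistic (both hypotheses share the constraint). A flag-free design
choice, documented here: the input tree supplies *relative* branch
lengths and only a global scale is estimated.

**Tests and posteriors.** `likelihood_ratio_test()` computes
$2\Delta\ell$ and a $\chi^2$ upper tail; negative statistics (possible
when an optimizer stalls) are flagged and reported with $p = 1$ rather
than hidden. For the branch-site test the conservative $\chi^2_1$
convention is the default, with the 50:50 mixture of a point mass at zero
and $\chi^2_1$ available via `mixture = TRUE`. Positively selected sites
are identified by naive empirical Bayes (posterior of the $\omega > 1$
classes at the MLEs); models without such a class (M0, M7) refuse the
query. Full Bayes empirical Bayes integration is not implemented; a
clearly labelled `gridBEB` option averages the NEB posterior over an
8-point grid that perturbs the selected-class proportion (factors 0.5,
1, 1.5) and its excess $\omega$ (factors 0.75, 1, 1.33), a coarse account
of parameter uncertainty.

## The simulator as the inverse model

`simulate_codon_alignment()` draws each site's class once at the root and
keeps it along the tree (the site-model assumption), samples root codons
from $\pi$ (or accepts a fixed root sequence), and evolves states edge by
edge with the matrix exponential of the same scaled generator used in
inference. A single integer seed determines all draws, in a documented
order (classes, root, then edges in cladewise order), and the caller's RNG
stream is restored afterwards. Indels, recombination, and rate variation
beyond the $\omega$-class structure are deliberately not simulated.

The remaining generators plant structure that downstream detectors must
recover exactly: genome layouts with tandem clusters occupying
consecutive-or-one-gap ordinal ranks (isolated family genes are kept at
least 3 ranks away from any other family gene so planted clusters are
precisely the maximal chains), expression matrices whose rows realize
their assigned specificity class, and promoters carrying an exact number
of planted motif copies with a rejection-sampled motif-free background.
What passing these round-trips shows is that the detectors implement their
definitions, not that real genomes are this clean: real tandem arrays can
abut by chance, real expression is noisy around the class boundaries, and
real promoters contain degenerate motif instances the IUPAC consensus
table only approximates.

## Family identification and protein statistics

A candidate is a family member when it has hits to both diagnostic Pfam
domains (defaults PF03330 and PF01357, expansin domains I and II) at
$E \le 10^{-10}$ and an *integral open reading frame*, operationalized as:
length divisible by 3, initial ATG, terminal stop, no internal stop. The
isoelectric point is the bisection root of the Henderson–Hasselbalch net
charge with the Bjellqvist-style pKa set used by the ExPASy tool
(including residue-specific N- and C-terminal values), converged to
$|q| < 10^{-4}$; molecular weight is the sum of average residue masses
plus one water. Signal peptides are annotation pass-through only — no
predictor is bundled.

## Phylogeny and subfamily assignment

Protein distances use pairwise gap deletion with either the p-distance
(default, the common choice for protein NJ) or the Poisson correction
$-\log(1-p)$. Trees come from Saitou–Nei neighbor joining (via ape), with
negative branch-length estimates clamped to zero with a warning. Bootstrap
support resamples alignment columns while preserving taxon order, so an
alignment of replicated columns reproduces the reference tree in every
replicate and all supports are 100 — taxon-order jumbling, which some
implementations use to randomize tie-breaking, is intentionally not done,
because it destroys this reproducibility contract.

Queries are labelled by the smallest bipartition side containing the query
and at least one reference leaf whose reference labels are monotypic;
failing that, the nearest reference leaf's label is used and the call is
flagged ambiguous.

## Duplication analysis and dating

Tandem clusters follow the adjacency rule: family genes on one chromosome
with at most one intervening gene between consecutive members (ordinal
gene ranks, not base-pair distance), reported as maximal chains of size
at least 2. Pairwise Ka/Ks uses Nei–Gojobori (1986) counting: fractional
synonymous sites from codon degeneracy with mutations to stop codons
counted as nonsynonymous, multi-hit codons averaged over equal-weight
minimal pathways that avoid stops, and the Jukes–Cantor correction
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$, which is undefined at
$p \ge 3/4$ and raises an error there. 4DTv is the raw transversion
proportion at third positions of fourfold-degenerate codons identical at
positions 1–2; no multiple-hit correction is applied, matching the use of
4DTv as a saturation-resistant relative-age proxy.

Segmental events are dated from collinear anchor-pair Ks values: anchors
are filtered to the open window $(0, 1)$, events with fewer than 3
surviving anchors are rejected, and the age is $T = \bar{K_s}/(2\lambda)$
with $\lambda = 6.1 \times 10^{-9}$ synonymous substitutions per site per
year (Fabaceae), reported in million years rounded to the nearest
integer. The sample (n−1) standard deviation accompanies the mean.
`anchors_from_summary()` reconstructs an anchor set with exactly a
published mean and standard deviation inside the window (a deterministic
two-point design), which lets published per-pair summaries be re-dated;
one benchmark row (mean Ks printed as 0.177) illustrates the limit of
this: the 3-decimal printed mean implies 14.5 My, on the boundary between
the printed age (14) and its neighbor (15).

## Functional divergence

Type-I divergence (rate shift after duplication) uses the classic
rate-correlation mixture on per-site parsimony substitution counts: with
probability $\theta_I$ a site draws independent $\Gamma(\alpha, \alpha)$
rates in the two clusters, otherwise one shared rate, with Poisson
likelihoods $x \sim \mathrm{Pois}(r\lambda)$ per cluster. Both mixture
components integrate to closed-form negative-binomial expressions, so
$\theta_I$, $\alpha$ and the cluster means are maximized directly by
restarted quasi-Newton optimization rather than EM — the same ML problem,
with the likelihood surface handled in closed form. The LRT against
$\theta_I = 0$ has 1 df; the per-site posterior $Q_k$ of the divergent
class drives critical-site calling, strict $Q_k > 0.95$ by default (0.80
is available but over-calls, which is why it is not the default). Clusters
with fewer than four sequences are refused, matching the standard
tooling's constraint. Fitch counts come from phangorn on the subtree
spanned by each cluster; non-monophyletic clusters are warned about, not
rejected.

Type-II divergence (property shift) is a moment contrast, not the full ML
treatment: sites whose residue sets are disjoint between clusters are
fixed differences; a fixed difference is radical when the cluster
consensus residues fall in different groups of a packaged charge/polarity
partition (positive KRH, negative DE, polar STNQCGYW, nonpolar AVLIMFP —
approximate, replaceable). With $f_R$ the radical fraction among fixed
differences and $p_0$ the radical fraction among within-cluster
polymorphisms (the baseline for an ordinary substitution),

$$\hat\theta_{II} = \frac{f_R - p_0}{1 - p_0},$$

reported unclamped — negative estimates are meaningful evidence of
*fewer* radical shifts than baseline — with a delta-method standard
error from the two binomial ingredients.

## Expression and promoters

RPKM is `count / (length/1000) / (library/1e6)`. Genes are clustered by
average-linkage agglomeration of $1 - r$ (Pearson) distances;
constant-profile genes (including silent, never-expressed ones) have
undefined correlation and are excluded with a warning rather than
imputed. Specificity classes are assigned in a fixed precedence order —
silent (all zero), single-tissue exclusive (exactly one nonzero),
constitutive (all nonzero), single-tissue peak, other — with the "marked
peak" quantified as the maximum tissue holding at least half the row
total, a threshold the qualitative literature leaves unstated; 0.5 was
chosen once as the weakest reading of "marked" and is a parameter.
Promoter scanning counts IUPAC consensus matches on both strands,
deduplicating a match and its reverse complement at the same start
(palindromes count once), counting overlaps, and reporting per-family
mean copies to three decimals. The packaged element table (G-box, Box4,
TCA-element, MBS, ARE, HSE, GARE-motif, circadian) holds approximate
consensi; curated definitions can be supplied as a replacement table.

## Numerical and testing choices

Problem sizes for the simulation-based checks were chosen to give each
statistic enough resolution while staying desk-scale: a 6-taxon balanced
tree with 0.3 substitutions/codon per branch for the selection suites
(one terminal foreground branch for branch-site runs); 100 codons and 200
replicates for the branch-site null-calibration study; 500 codons, 10%
of sites at foreground $\omega_2 = 4$, and 50 replicates for power; 300
codons and 20 replicates for one-ratio $\omega$ recovery; 500 sites,
$\theta_I = 0.6$, $\alpha = 0.5$ and per-cluster Poisson means of 2
(typical parsimony-count magnitudes for subfamily-sized subtrees) for
type-I recovery. Oracles are independent routes: Higham matrix
exponentials, exhaustive internal-state enumeration, pathway enumeration,
closed-form $\chi^2$ tails for even df, brute-force linkage, and
fine-grid charge scans.

Known limitations: no indel model and no alignment step (alignments are
inputs); NG86 is downward-biased at strong transition/transversion bias
(it is the desk-verifiable counting method; the likelihood engine is the
reference for model-based estimates); the branch-site $\chi^2_1$
convention is conservative; gridBEB is a labelled approximation, not BEB;
type-II divergence is a moment estimator and will not reproduce full-ML
outputs numerically; and the cis-element table is approximate by design.
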