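# famevol

Gene-family expansion and molecular-evolution analysis in R.

Plant gene superfamilies — the expansins (cell-wall loosening proteins
with subfamilies EXPA, EXPB, EXLA, EXLB) are the motivating case — grow
by tandem and segmental duplication, and their duplicates then diverge in
sequence, expression and function. famevol packages the full analysis
chain a study of such a family runs, for people who would otherwise
stitch it together from half a dozen tools:

* **Family identification** — two-domain Pfam evidence (PF03330 +
  PF01357) at E ≤ 1e-10 plus an integral-ORF check; theoretical pI
  (Henderson–Hasselbalch bisection, ExPASy-style pKa set) and molecular
  weight.
* **Phylogeny** — p-distance / Poisson protein distances with pairwise
  gap deletion, Saitou–Nei neighbor joining, column-resampling bootstrap,
  and subfamily assignment of query genes from reference-labelled leaves.
* **Duplication history** — tandem clusters under the "at most one
  intervening gene" adjacency rule; Nei–Gojobori (1986) Ka/Ks with
  Jukes–Cantor correction; 4DTv (raw transversion rate at fourfold
  degenerate sites); segmental-event dating from anchor Ks values via
  `T = Ks / (2λ)` with λ = 6.1e-9 /site/year.
* **Selection** — a GY94 codon likelihood engine (Felsenstein pruning
  over the 61 sense codons) with site models M0 / M3 / M7 / M8, the
  branch-site model A with its ω₂ = 1 null, likelihood-ratio tests, and
  NEB (plus a labelled grid-prior "gridBEB") identification of positively
  selected sites.
* **Functional divergence** — type-I θ (rate-shift mixture on Fitch
  parsimony counts, closed-form negative-binomial likelihood) and type-II
  θ (radical property-shift moment contrast), per-site posteriors Qk and
  strict Qk > 0.95 critical-site (CAAS) calling.
* **Expression & promoters** — RPKM normalization, Pearson-correlation
  average-linkage clustering, tissue-specificity classes (constitutive /
  exclusive / peak / silent / other), and both-strand IUPAC cis-element
  scanning with a small packaged motif table.
* **Synthetic data** — seeded generators for codon alignments evolved
  under any of the selection models (the exact inverse of the inference
  engine), genome layouts with planted tandem/segmental structure,
  expression matrices with planted specificity classes, and promoters
  with planted motif copies. Every detector is tested by round-tripping
  these plants.

## A worked example

Simulate a small family under positive selection on one lineage, then ask
the branch-site test whether it notices:

```r
library(famevol)
library(ape)

tree <- read.tree(text = "((a:0.3,b:0.3):0.3,(c:0.3,d:0.3):0.3,(e:0.3,f:0.3):0.3);")
fg   <- which(tree$edge[, 2] == which(tree$tip.label == "a"))

spec <- sim_model_spec("branch_site_A", kappa = 2, p0 = 0.8, p1 = 0.1,
                       omega0 = 0.2, omega_s = 4,
                       foreground_branches = fg, seed = 101)
sim <- simulate_codon_alignment(tree, spec, n_codons = 500)

fit <- fit_branch_site(sim$alignment, tree, foreground = fg, seed = 1)
fit
#> Branch-site model A
#>   lnL (alt) = -6693.7387   lnL (null, omega2 = 1) = -6700.4969
#> LRT: 2*dlnL = 13.5164  df = 1  p = 0.0002365
#>    proportion background foreground
#> 0     0.75607    0.18242    0.18242
#> 1     0.11097    1.00000    1.00000
#> 2a    0.11594    0.18242    3.98905
#> 2b    0.01702    1.00000    3.98905
#>   positively selected sites (posterior > 0.95): 36, 116, 172, 195, 315, 371, 379
```

The fitted class table mirrors the 0 / 1 / 2a / 2b structure of the
model: most sites purifying (ω₀ ≈ 0.18), about 13% of sites switching to
ω₂ ≈ 4.0 on the foreground branch (the simulator planted 10% at ω₂ = 4),
and a likelihood-ratio statistic of 13.5 on 1 df — the planted foreground
selection is detected at p < 0.001, with seven sites called by naive
empirical Bayes at posterior > 0.95.

Dating a segmental duplication from its collinearity anchors:

```r
ev <- date_segmental_event(c("GmEXPA22", "GmEXPA49"),
                           anchor_ks = c(0.095, 0.118, 0.087, 0.104, 0.112, 0.084))
ev
#> Segmental event GmEXPA22 & GmEXPA49: 6 anchors, Ks = 0.100 +/- 0.014, ~8 My
```

A mean Ks of 0.100 under the Fabaceae synonymous clock corresponds to a
duplication roughly 8 million years ago — the age scale of the younger
soybean whole-genome duplication.

## Scope

Alignments, domain-hit tables and synteny anchors are *inputs*: famevol
does not run BLAST/HMMER, build multiple alignments, call synteny blocks,
or predict signal peptides. The methods vignette
(`vignettes/famevol-methods.Rmd`) documents every model, default and
design decision, and the known limitations.
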