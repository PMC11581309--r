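---
title: "Methods: pairwise divergence, selection tests and E-R correlation in cadevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise divergence, selection tests and E-R correlation in cadevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadevo)
```

## Scope and data model

cadevo analyses the comparative evolution of an ortholog family with a
shared domain architecture — written around the classical cadherins
(CDH), single-pass adhesion glycoproteins with five extracellular EC
repeats (EC1–EC5) and a cytoplasmic domain (CD). Every analysis is
pairwise: a human reference sequence against one other species at a time.
The package consumes externally produced protein alignments together with
the matching coding sequences; it never runs an aligner itself, because
wrapping one adds nothing to the statistics and keeps the package free of
a system dependency. Domain coordinates are 1-based inclusive positions
on the *mature* human protein (signal peptide and pro-domain removed), so
`FL` runs from the first residue of EC1 to the last residue of the CD.
Alignment columns where the human row is gapped are assigned to the
domain of the preceding human residue, so insertions relative to the
reference stay with their segment; this is one reasonable convention for
a case the coordinate system leaves open.

Gap and ambiguity handling follows pairwise deletion: for each sequence
pair, any column carrying a gap or an ambiguity code (X, N, ...) in
either row is removed; in codon mode one masked position removes the
whole codon. Terminal stop codons on a CDS are trimmed with a note;
internal stops are hard errors, since a mature coding sequence is
expected.

## Protein distances

`p_distance` is the proportion of differing retained columns — a
diagnostic companion, not a corrected distance. `jtt_distance` is the
maximum-likelihood pairwise distance under the empirical JTT model with a
uniform substitution rate across sites (no gamma heterogeneity, matching
the uniform-rate analysis the pipeline implements): it maximizes

$$\ell(t) = \sum_{\text{sites}} \log\big(\pi_{a_i}\,P_{a_i b_i}(t)\big),
\qquad P(t) = e^{Qt},$$

over $t \in [0, 10]$ with tolerance $10^{-6}$, where $Q$ is the JTT
generator built from the published exchangeabilities and equilibrium
frequencies bundled as a plain-text file in the PAML `jones.dat` layout,
normalized to one expected substitution per site per unit time. The
model's "+F" option is off: the published equilibrium frequencies are
used. Because the model is reversible, the choice of conditioning row is
immaterial and the distance is exactly symmetric. Identical retained
columns return exactly 0; an optimum pinned at the upper bound is
reported as a saturated flag rather than an error. The test suite checks
the optimizer against a dense grid search with step $10^{-4}$, and checks
consistency by re-estimating pairs simulated under the same model.

## Codon-level divergence and selection

The primary estimator is the degeneracy-class (Pamilo–Bianchi–Li style)
method with Kumar-type site classification. Each position of each sense
codon is nondegenerate (class 0), twofold (2) or fourfold (4): fourfold
if all three alternative bases are synonymous, nondegenerate if none is,
twofold otherwise — a convention that sends the irregular isoleucine and
arginine families to the twofold class and counts changes to stop codons
as nonsynonymous. Site totals $L_0, L_2, L_4$ are averaged over the two
sequences and always satisfy $L_0+L_2+L_4 = 3\,n_{\text{codons}}$.

Differences between codons differing at $k \in \{1,2,3\}$ positions are
averaged over all $k!$ orderings of single-base steps with equal weights;
pathways through stop codons are excluded, and a pair whose every pathway
hits a stop is dropped with a note. A step at a position whose class
differs between its two codons contributes half to each class. With
per-class transition and transversion proportions $P_i, Q_i$:

$$A_i = -\tfrac12\ln(1-2P_i-Q_i) + \tfrac14\ln(1-2Q_i), \qquad
  B_i = -\tfrac12\ln(1-2Q_i),$$

$$d_S = \frac{L_2 A_2 + L_4 A_4}{L_2 + L_4} + B_4, \qquad
  d_N = A_0 + \frac{L_0 B_0 + L_2 B_2}{L_0 + L_2}.$$

Variances are delta-method over the per-class $(P_i, Q_i)$ with
multinomial covariances ("analytical formula"; no bootstrap is needed for
the reported tests). The Z-test of strict neutrality uses
$Z = (d_N - d_S)/\sqrt{V_N + V_S}$ with a two-tailed normal p for the
neutral alternative and one-tailed p's for negative ($d_N < d_S$) and
positive ($d_N > d_S$) selection. For small difference counts the Fisher
exact test is applied to the $2\times2$ table of Nei–Gojobori style
counts $[[N_d, N-N_d],[S_d, S-S_d]]$, with fractional pathway-averaged
counts rounded half away from zero — a stated choice, since exact-test
integerization conventions differ between implementations.

A modified Nei–Gojobori estimate (transition-weighted site counts with
the transition/transversion ratio estimated from the pooled Kimura
two-parameter components, Jukes–Cantor corrected) is attached to every
result as a built-in cross-check; the two estimators are not identical
but agree within 0.05 on simulated data with $\kappa \in [1, 4]$, which
the suite asserts. Which of the two conventions a given MEGA release
labels "Kumar's method" is ambiguous, so both are always computed and the
package's guarantees rest on simulation recovery, not bit-equality with
any external tool.

## The codon-pair simulator

`simulate_codon_pair` evolves two lineages from a common ancestor drawn
from a configurable codon distribution (uniform over the 61 sense codons
by default — deliberately neutral rather than realistic, which is the
right property for unit tests). Single-base changes arise with relative
rate $\kappa$ for transitions and 1 for transversions; changes creating
stops are rejected; nonsynonymous changes are thinned by $\omega$. This
mutation–selection construction was chosen over exponentiating a
$61\times61$ generator because it yields an event log: every accepted
event is recorded, so tests can replay the log against the output
sequences and reconcile realized synonymous/nonsynonymous counts. Branch
length is calibrated so one unit equals one expected synonymous
substitution per ($\kappa$-weighted) synonymous site under the ancestor
distribution; the default 0.1 per lineage gives pairwise $d_S \approx
0.2$.

Parameter recovery holds within $\pm 0.05$ of planted $\omega \in \{0.1,
0.2, 1.0\}$ at 10,000 codons. A known limitation: under neutrality the
degeneracy-class estimator converges to $\hat\omega \approx 0.96$ rather
than 1 on this process, because stop-codon rejection depresses realized
nonsynonymous changes at class-0 sites while fourfold sites are
unaffected, and a handful of twofold-class sites have synonymous
transversions. The bias grows with divergence, so the Z-test's type-I
error is calibrated at the divergence where the test is actually
deployed on near-neutral pairs: 700-codon sequences (full-length mature
cadherin scale) at pairwise $d_S = 0.04$ (ape–human scale), where both
one-sided rejection rates sit near the nominal 0.05. At pairwise $d_S
\approx 0.2$ the negative tail inflates to roughly 0.09 — worth knowing
when interpreting marginal negative-selection calls for distant species.

## Nonparametric statistics

All group comparisons are rank-based, implemented from the defining
formulas with mid-ranks for ties throughout (the tie convention is a
package choice): Kruskal–Wallis with tie-corrected $H$ and a chi-square
reference; Dunn's pairwise $z$ tests on the joint ranks with the pooled
tie term, two-tailed p's, Holm step-down adjustment over all pairs
(two-tailed before adjustment, the common R/SPSS convention);
Mann–Whitney U with the exact enumerated null distribution when
$\min(n_1, n_2) \le 8$ and no ties (configurable), otherwise the
tie-corrected normal approximation, two-sided p doubling the smaller
tail; Spearman correlation as the Pearson correlation of mid-ranks with
a t approximation on $n-2$ degrees of freedom and an exact permutation
option for $n \le 9$. The suite cross-checks every one of these against
the corresponding base-R implementation, and checks the t approximation
against the exact permutation p — at $n = 5$ the two can differ by up to
about 0.08 for strong correlations, so small-sample p's near a threshold
should use the exact option.

## Essentiality and expression–rate correlation

The essentiality score is the deterministic composite: knockout
non-lethal 0 / lethal 2; phenotype none 0 / mild 1 / severe 2; human
disease association 0/1; maximum 5. Severity has no operational
definition beyond the curated input, so the package takes the annotation
file as given; the live phenotype-database query that would produce it is
documented but deliberately not automated, since database state drifts.

E-R profiling computes one two-tailed Spearman correlation per expression
sample (tissue or cell type) between a per-gene metric (dN, dN/dS or
LOEUF) and that sample's expression values, matched by symbol
case-insensitively; expression is used exactly as provided, with no
re-normalization, because the correlations are rank-based anyway.
Class-level summaries report the fraction of samples with $p < \alpha$
(default 0.05) and the requested sign; the any-species mode calls a
sample significant when at least one species' metric vector yields a
significant correlation, which is the aggregation needed to state that a
cell type is significantly anti-correlated "with at least one species".
With 17 genes and planted class correlations of $\mp 0.6$, the sign is
recovered in over 95% of samples, and a null-planted matrix yields a
significant fraction near $\alpha$ with approximately uniform p-values.

The synthetic expression generator uses a Gaussian copula (Pearson
parameter $r = 2\sin(\pi\rho_s/6)$ for a Spearman target $\rho_s$)
mapped through `exp()` to nonnegative abundances; targets of exactly
$\pm 1$ produce rank-preserving transforms. It emulates the rank
structure of tissue/cell-type panels but none of the mean-variance,
sparsity or correlated-sample structure of real expression atlases — so
passing tests demonstrate the statistics, not robustness to real
single-cell noise.

## Problem sizes and defaults

The shipped defaults are the study conditions the package is tested
under: $\kappa = 2$, pairwise $d_S \approx 0.2$ for recovery experiments
(10,000 codons), ape-scale divergence for test calibration (700 codons,
$d_S = 0.04$), a 13 CNS / 39 non-CNS sample layout with 17 genes for E-R
experiments, and a nine-species divergence table whose group mean times
are 10.9, 27.5 and 48.7 MYr. The end-to-end synthetic study uses four
genes of 701 codons with planted $\omega \in \{0.1, 0.2, 0.5, 0.9\}$ and
a per-domain substitution rate of $10^{-3}$ per MYr. `mean_rate_per_myr`
reports the mean of per-species distance/time ratios in percent (the
mean-of-ratios reading; figures built from group averages of pairwise
comparisons suggest this over a regression slope), with the least-squares
slope alongside for transparency.

## Degenerate inputs and numerical choices

Zero comparable sites or codons raise errors naming the cause; saturated
log arguments flag the result rather than throwing; $d_S = 0$ marks
$\omega$ undefined; zero-variance Z-tests with $d_N = d_S$ return $p = 1$;
constant vectors mark Spearman reports undefined rather than NA-silent.
Likelihood evaluations clip transition probabilities at $10^{-300}$
before logging; the K2P delta-method variance uses the standard
$c_1, c_2, c_3$ coefficients and reduces exactly to Jukes–Cantor when
$P = p/3, Q = 2p/3$, which the suite asserts to $10^{-12}$.
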