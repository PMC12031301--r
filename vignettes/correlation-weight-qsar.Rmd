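---
title: "Correlation-weight optimal descriptors for SMILES-based QSAR"
author: "cwqsar maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weight optimal descriptors for SMILES-based QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwqsar)
```

## The model

`cwqsar` builds QSAR models without computed molecular descriptors: the
model works directly on the SMILES string. Each molecule is reduced to a
multiset of string attributes, every attribute carries one tunable real
number (its *correlation weight*, CW), and the molecular descriptor is the
sum

$$DCW(T, N) = \sum CW(S_k) + \sum CW(SS_k) + \sum CW(SSS_k)
           + \sum CW(FLS) + \sum CW(APP),$$

over five attribute families: single tokens ($S_k$), adjacent token pairs
($SS_k$) and triples ($SSS_k$), *fragments of local symmetry* (FLS — token
windows shaped XYX, XYYX or XYZYX with $X \neq Y$ and, for XYZYX,
$Y \neq Z$), and *atom-pair proportions* (APP — a ten-level discretization
of the count ratio of two element types). $T$ (the blocking threshold) and
$N$ (the number of optimization epochs) are the two structural parameters:
attributes seen in fewer than $T$ active-training molecules are *blocked*
and contribute exactly zero.

The endpoint model is the univariate least-squares line

$$\hat{y} = C_0 + C_1 \cdot DCW,$$

refit after every weight move. For binary endpoints the same line is used
as a *semi-correlation* classifier: a molecule is called active exactly
when $\hat{y} \ge 0.5$.

## Tokenization

The tokenizer is purely lexical. Two-character units are never split:
`Cl`, `Br`, `@@`, and `%NN` ring closures; a bracket expression `[...]` is
one token; everything else — including ring digits, parentheses and bond
symbols — is a single-character token. Concatenating the tokens reproduces
the input exactly, and no chemistry (valence, aromaticity) is checked:
the method's premise is that the string statistics carry the signal.

Pair and triple keys are canonicalized by byte-order sorting of their end
tokens, so attribute extraction is invariant under reversal of the string.
FLS keys are class-level by default (`[xyx0]`, `[xyyx0]`, `[xyzyx0]`): all
fragments of one shape share a weight, which mirrors how such attributes
are reported in practice; a configuration switch
(`attrConfig(flsContent = TRUE)`) yields content-qualified keys instead.
The APP discretization `r = round(10 * min(nX, nY) / max(nX, nY))`,
clamped to at least 1, is a deliberately coarse reading of "atom pair
proportions"; it is documented as approximate.

## The influence kernel and the model-quality criteria

All the nonstandard criteria derive from one kernel: the leave-one-out
influence of each observation on the Pearson correlation of a paired
series,

$$\Delta_k = r_{-k} - r.$$

Observations with $\Delta_k > 0$ are *opponents* of the correlation
(removing them improves it); $\Delta_k < 0$ marks *supporters*. The
kernel is computed by an $O(n)$ downdate of the five sufficient sums and
is oracle-tested against the $O(n^2)$ recomputation at $10^{-10}$.

From the kernel:

* **CII** (correlation intensity index): $1 - \sum_{\Delta_k > 0} \Delta_k$.
  Equal to 1 when nothing opposes the correlation; larger is better.
* **CCCP** (coefficient of conformism of a correlative prediction):
  $1 - \sum_{\text{opponents}} \Delta_k \big/ \sum_{\text{supporters}} |\Delta_k|$.
  Equal to 1 with no opponents, 0 when the two masses balance, negative
  when opponents dominate. When a series has no supporters the ratio is
  undefined; the package reports `NA` rather than a silently wrong number.
  The literal opponent/supporter ratio is available via
  `cccp(d, form = "ratio")`.
* **IIC** (index of ideality of correlation):
  $r \cdot \min(\mathrm{MAE}^-, \mathrm{MAE}^+) / \max(\mathrm{MAE}^-, \mathrm{MAE}^+)$,
  where the two MAEs are taken over negative- and non-negative-residual
  observations. A numerically zero residual vector is treated as an exact
  fit (both MAEs vanish together, so IIC $= r$); this boundary rule
  matters, because without it near-perfect models evaluate as undefined
  and an optimizer would reject exactly the states it is looking for.

The influence statistic defaults to Pearson $r$; `looInfluence(...,
statistic = "r2")` provides the squared-correlation variant behind a
switch, since either reading of "correlation coefficient" is defensible.

Standard criteria (R², Lin's CCC, RMSE, MAE, $F = R^2(n-2)/(1-R^2)$,
leave-one-out $Q^2$ via the PRESS/hat-value identity, and the
confusion-matrix statistics with the determinant-form MCC) are implemented
with their textbook definitions and tested against independent
formula-by-formula oracles, including an explicit refit-per-deletion PRESS
loop for $Q^2$.

## Monte Carlo optimization

Weights are tuned to maximize one of two target functions, with IIC, CII
and CCCP evaluated on the calibration set:

$$T_1 = R_A + R_P - |R_A - R_P| \cdot F_1 + (IIC + CII) \cdot F_2$$
$$T_2 = T_1 + CCCP \cdot F_3,$$

with $F_1 = F_2 = 0.5$ and $F_3 = 0.3$ by default. $R_A$ and $R_P$ are the
observed-vs-predicted correlations on the active and passive training
sets. Only $A$ and $P$ enter the regression fit; the calibration set
steers the search through the criteria; the validation set is never read
during training (the test suite asserts that shuffling validation
endpoints leaves the trained weights bit-identical).

The search itself is a strict-improvement coordinate Monte Carlo:

* **Initialization.** Non-blocked weights start at 0 plus uniform jitter
  in $[-0.1, 0.1]$. Growing weight mass from zero is a stagewise path
  that adds descriptor complexity only where the target demands it — an
  implicit regularizer in an attribute space that can easily carry several
  weights per training molecule. Five *warm-up sweeps* then ascend the
  pure training-correlation surface ($F_2 = 0$) before the scored epochs
  begin, placing the start on the correlation ridge where the non-smooth
  criteria act as fine-tuning rather than as a barrier.
* **Proposals.** Each epoch visits the non-blocked attributes in a fresh
  seeded random order. A visit draws three magnitudes log-uniformly from
  $\delta \cdot [1/64, 16]$ (default $\delta = 0.1$) and tries each in
  both directions; the first strictly improving step is accepted and then
  greedily extended in the same direction with doubling stride while the
  target keeps improving. Improvement must exceed a $10^{-9}$ margin: the
  target is scale-invariant in the weights up to the refit, so exact ties
  are common and float noise must not masquerade as progress.
* **Degenerate moves.** A proposal that makes any component undefined —
  zero-variance descriptor, one-sided residuals, no supporters under
  $T_2$ — is treated as non-improving, not as an error.
* **Orientation.** After the run the model is oriented so $C_1 > 0$
  (flipping all weights and the slope leaves every prediction unchanged);
  CW signs are then comparable across runs, which is what makes promoter
  extraction meaningful.

Why not a fixed step? A fixed-step strict-ascent kernel provably traps at
the start on this target: the criteria terms create barriers that no
single move at one scale can cross, while a multi-scale randomized kernel
crosses them at some scale on some epoch. Even so, convergence saturates
slightly below the theoretical target supremum: near the optimum the
correlation gains of a single move shrink to zero while IIC/CII on a
calibration set of $n_C$ molecules jump by $O(1/n_C)$ whenever an
opponent/supporter or residual-sign membership flips. This *statistical
friction* bounds how closely any strict-improvement single-coordinate
search can approach a perfect fit; in practice calibration R² plateaus
around 0.98–0.99 on noise-free synthetic data.

`extractPromoters()` compares several runs under identical configuration
and different seeds and returns the attributes whose CW is strictly
positive in all of them — the stable "promoters" of endpoint increase.

## Splits, statistical defects and the applicability domain

Data are structured into four subsets: active training (weights are
tuned on its correlation), passive training (a consistency check inside
the target), calibration (criteria), validation (never seen). The default
split is equal quarters by a seeded shuffle-and-cut with cumulative
rounding.

The *statistical defect* of an attribute measures how unevenly it is
represented across $A$, $P$ and $C$:

$$d_k = \frac{|P - P'|}{N + N'} + \frac{|P - P''|}{N + N''}
      + \frac{|P' - P''|}{N' + N''},$$

with $P$-terms the fraction of molecules containing the attribute and
$N$-terms the molecule counts. Counting is per molecule, not per
occurrence — the formula does not distinguish the two, and per-molecule
counting makes $P$ a proper prevalence. A molecule's defect $D_j$ sums the
$d_k$ of its distinct non-blocked attributes, and a molecule is in the
applicability domain when $D_j < 2\bar{D}$, with $\bar{D}$ averaged over
the structured training set ($A \cup P \cup C$) so that validation and
new molecules are judged against the training baseline. When every defect
is zero the strict inequality would exclude everything, so that degenerate
case is defined as all-in-domain. The domain is advisory: predictions are
reported for out-of-domain molecules, flagged.

The *Las Vegas* search draws `nTests` random splits, runs a short probe
optimization on each (same target variant as the final run, fewer
epochs), and keeps the split with the largest calibration R². The trace
records, per probe, the attribute-partition census — `NAll` distinct
attributes in $A$; `N111/N110/N101/N100` for presence in (A,P,C) —
together with the probe's CCCP and subset R² values and the running best.
A failed probe is recorded with calibration R² 0 and does not abort the
search. Defect-greedy split construction (building a split to minimize
total defect directly) is deliberately not attempted; random search
scored by calibration performance is the implemented reading.

## The synthetic benchmark

Real endpoint collections cannot ship with the package, so the test bed
is a generator with known ground truth. Two design points matter:

* **Fragment-based molecules.** Molecules are concatenations of a fixed
  library of ~20 organic fragments (aromatic rings, alkyl runs,
  heteroatom links), optionally branch-wrapped, up to an atom budget of
  4–20 atoms. This mimics a statistical property of real compound
  collections that independent random tokens badly violate: the attribute
  vocabulary is compact and heavily shared between random subsets (a few
  hundred distinct attributes per hundred molecules, most present in all
  of $A$, $P$ and $C$). With independently sampled tokens the attribute
  space is several times larger and dominated by singletons, and any
  weight optimizer drowns in spurious rare attributes — a regime real
  drug-like data does not present. A token-chain mode
  (`generateSmiles(motifs = NULL)`) remains available.
* **Endpoint linear in single-token counts.** The latent endpoint is
  `4 + sum(trueWeights * token counts)` with Gaussian noise (default sd
  0.3), giving a pIC50-like scale with latent sd near 1. Only single
  tokens carry true effects, so the pair/triple/FLS/APP families are pure
  nuisance — the benchmark deliberately tests that the optimizer tolerates
  irrelevant attribute families. For classification, molecules are
  labelled by a median split of the latent value, which keeps classes
  balanced for any weights.

What passing tests do and do not show: the benchmark demonstrates
recovery of planted linear structure, correct bookkeeping, and the
direction of the $T_2$-vs-$T_1$ comparison under nuisance attributes and
noise. It does not demonstrate chemical validity handling, activity
cliffs, scaffold-level generalization, or the label noise and assay
heterogeneity of real hERG data.

The problem sizes used throughout the tests — 200 molecules for
regression, 400 for classification, 30 epochs, 10-seed replications —
were chosen to mirror the regression database scale (≈400 compounds
split into quarters) while keeping a full suite run in the low minutes.

## Numerical choices and edge rules

* Degenerate inputs raise typed errors (`degenerate_data`,
  `degenerate_descriptor`, `undefined_cccp`, `undefined_iic`,
  `undefined_defect`, `split_error`, `parse_error`) rather than returning
  wrong numbers; reporting paths convert undefined CCCP/IIC to `NA`.
* A perfect fit reports $F = \infty$ and $Q^2 = 1$; CCCP on an exact line
  is `NA` (every deletion leaves $r = 1$, so there are no supporters).
* MCC with a zero denominator is reported as 0 and flagged.
* All randomness (splits, initialization, proposal magnitudes, epoch
  orders, generator draws) flows through per-call seeds; the same seed
  reproduces a run bit-identically, and model JSON serialization keeps 17
  significant digits so a round trip preserves predictions exactly.
* Blocking threshold $T$ defaults to 5 active-training molecules:
  selected, as the method itself prescribes for its structural
  parameters, by calibration-set performance on the benchmark; $T = 1$
  (no blocking beyond absence) measurably collapses validation skill.

## Known limitations

* The strict-improvement search saturates below the target supremum (the
  statistical-friction plateau above); squeezing the last fraction of a
  percent of calibration R² would require accepting ties or non-improving
  moves, which the method as described does not do.
* Semi-correlation classification with the fixed 0.5 cutoff inherits the
  regression's recovery precision; on a zero-margin (median-split)
  boundary, validation sensitivity/specificity saturate around 0.94 on
  the benchmark.
* The tokenizer covers common organic SMILES; exotic multi-character
  units beyond `Cl/Br/@@/%NN/[...]` would need vocabulary extensions.
* Attribute keys treat the SMILES as written: no canonicalization means
  the same molecule written two ways yields different attribute bags.
  This is a property of the method, not an accident.
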