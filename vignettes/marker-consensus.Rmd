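---
title: "Cross-individual brain-region marker discovery with mRMR and revised IFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-individual brain-region marker discovery with mRMR and revised IFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmarker)
```

## The problem

Bulk expression profiles of the human brain separate cleanly by region
within one person: brain stem (BS), cerebellum (CB) and cerebral cortex
(CC) samples differ in thousands of genes. The harder and more useful
question is which genes discriminate regions *robustly across people*,
rather than reflecting one individual's idiosyncratic expression.
`regmarker` implements a pipeline for that question on multi-donor
cohorts shaped like the public six-donor brain atlases: per donor, a
genes-by-samples intensity matrix with strongly imbalanced region classes
(cortex samples dominate, cerebellum is smallest).

The design is deliberately cross-individual. Every donor in turn serves as
the *training* individual; classifiers built from that donor's data alone
are evaluated on every *other* donor's samples, and only genes that keep
their discriminative power across this transfer enter the final consensus.

## Pipeline overview

For each training donor $d$:

1. **Discretize** $d$'s expression gene-wise into three states.
2. **Rank genes** by minimum-redundancy maximum-relevance (mRMR) mutual
   information against the region label, keeping the MaxRel ranking
   alongside.
3. **Revised incremental feature selection (IFS):** for each prefix
   $F_k = \{f_1, \dots, f_k\}$ of the mRMR list, train a one-vs-one linear
   SVM on $d$'s raw expression restricted to $F_k$ and score it on each
   other donor, giving one accuracy-vs-$k$ curve per test donor.
4. **Inflection points:** on each curve pick the first $k$ whose accuracy
   is no worse than its predecessor and strictly better than its
   successor.
5. **Important features of $d$:** the intersection of the selected
   prefixes over test donors.

Finally the **consensus table** counts, per gene, how many donors'
important sets contain it; genes with high frequency are the robust
region markers.

## The synthetic cohort generator

Real multi-donor atlas data require a large external download and carry
unstated preprocessing; the generator supplies cohorts whose ground truth
is known, so every stage (and the whole pipeline) is testable. Gene $g$
has a shared baseline $\mu_g \sim N(0,1)$; donor $d$ adds a per-gene batch
offset $b_{dg} \sim N(0, \sigma_b^2)$; a sample from region $r$ measures

$$x = \mu_g + b_{dg} + \delta_{gr} + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma_\varepsilon^2),$$

with $\delta_{gr} = \text{effect\_size} \cdot \sigma_\varepsilon$ when $g$
is planted for $r$ and $0$ otherwise. Defaults emulate the six-donor
design: the published per-region sample counts (363, 529, 470, 501, 946,
893 samples per donor), 2000 genes as a test-scale stand-in for a full
~20,782-gene microarray profile, 10 planted genes per region shared by
all donors, effect size 2 (a clear but not trivial shift, two noise
standard deviations), batch sd 0.5 (cross-donor transfer is noticeably
harder than within-donor classification, as in real atlas data) and
noise sd 1. Planted sets for the three regions are disjoint; a
`private_planting` switch plants donor-specific sets instead, emulating
genes that discriminate in only some individuals.

What the generator does *not* emulate: probe-level artifacts, intensity
distributions of real microarrays (values are Gaussian, not log-intensity
shaped), spatially correlated sampling within a region, correlated gene
modules, and donor-specific class proportions beyond the fixed counts.
Passing tests therefore demonstrate the pipeline's mechanics and its
recovery of additive region shifts under batch noise — not performance on
real atlas intensities.

Reproducibility: one seed drives everything; per-donor sub-streams are
derived deterministically from it, so cohorts are bit-identical however
the donors are materialized.

## Discretization and mutual information

Mutual information on continuous intensities needs a discretization
convention. Following the long-standing practice of mRMR on microarray
data, each gene is coded relative to its own mean $m_g$ and standard
deviation $s_g$ *within the dataset being ranked*:

$$\text{state} = \begin{cases} -1 & x < m_g - t\, s_g \\ +1 & x > m_g + t\, s_g \\ 0 & \text{otherwise,} \end{cases}$$

with threshold $t = 1$ by default ($s_g$ is the sample standard
deviation; a constant gene maps to all zeros). Mutual information is the
plug-in estimate over the joint contingency table, in bits; the base only
scales scores and never changes a ranking.

MaxRel sorts genes by $I(g; \text{class})$ alone. mRMR selects greedily:
the first gene maximizes relevance; thereafter gene $g$ maximizes

$$I(g; c) \;-\; \frac{1}{|S|}\sum_{s \in S} I(g; s)$$

over the already-selected set $S$ (the *difference* criterion, the
canonical "max-relevance minus min-redundancy" form; a *quotient*
criterion is available behind a flag, with the redundancy denominator
floored at $10^{-12}$). All ties — in relevance or in the greedy
objective — break by ascending gene id, so lists are identical across
platforms. The greedy prefix property matters later: the first $k$
entries of an mRMR list of any length are the same, so computing a longer
list never changes a shorter one's prefix.

## The prediction engine

The classifier is a linear soft-margin SVM trained by sequential minimal
optimization (SMO): the dual quadratic program is solved by repeatedly
optimizing the smallest possible working set of two dual variables
analytically, with a first-violator outer loop alternating full passes
and non-bound passes, and a deterministic largest-$|E_1 - E_2|$ second
choice. After the loop the bias is recomputed from the KKT-feasible
interval (mean of the interior support vectors' margin equations, or the
interval midpoint when every $\alpha$ sits at a bound — the running
per-step bias need not satisfy all constraints in that degenerate case).

Engine parameters mirror common toolkit defaults and are exposed:
$C = 1$, tolerance $10^{-3}$, linear kernel, internal standardization of
each feature by the training mean and *population* (1/n) standard
deviation, with constant features passed through unscaled. (The
discretizer uses the sample standard deviation, the usual convention for
that coding; the two conventions are each pinned by their own closed-form
test cases.) $\alpha$'s within $10^{-8}$ of a bound are treated as
at-bound. Three classes are handled one-vs-one: models for BS|CB, BS|CC
and CB|CC each vote; majority wins, vote ties break by the larger sum of
absolute decision values over the tied classes, then by label order
BS < CB < CC; a zero decision value within one binary model goes to the
pair's first label. A pair whose training data lack one class degrades to
a constant predictor for the present class, so two-class inputs reduce
exactly to the informative binary model.

The SVM consumes raw expression, not discretized states; discretization
exists solely for the mutual-information ranking.

## Revised IFS, inflection points, consensus

The IFS curve for (train $d$, test $d'$) evaluates $k = 1..n$. Accuracy
comparisons in the inflection rule are made on exact correct-sample
counts (the denominator is constant along one curve), so the $\geq$ / $>$
conditions never hinge on floating-point representation. The inflection
point is the smallest $k$ in a search window $[k_{\min}, k_{\max}]$
(default $[4, 50]$, matching the region of the curves worth magnifying;
the rule itself is window-free) with
$\text{acc}(k) \geq \text{acc}(k-1)$ and
$\text{acc}(k) > \text{acc}(k+1)$. A strictly rising or flat window has
no such point; the detector then falls back to the smallest argmax in the
window and flags `fallback_used`, so downstream consumers can exclude
fallback selections.

Because prefix sets of one list are nested, the intersection of the five
selected prefixes equals the prefix of the minimum selected $k$;
`important_features()` performs the literal intersection *and* the
min-$k$ shortcut and asserts they agree before returning. The consensus
table counts contributing donors per gene and sorts by frequency, then
gene id.

A consequence of the prefix-nestedness plus the search window: curve
points beyond $k_{\max} + 1$ can never influence the consensus. The
fitting function `ifs_consensus()` therefore exposes `n_curve` and the
package's own analyses compute curves to $k_{\max} + 1 = 51$ from a
60-entry mRMR list; the result is provably identical to computing all
500 points, at a twelfth of the cost. The 500-set structure itself is
exercised separately in the test suite on a small cohort. Full-scale
tests use the default 2000-gene cohort with the published sample counts;
the determinism contract (byte-identical artifact manifests across
reruns) is exercised at 300 genes.

## Numerical and design choices

* **Tie-breaks** are total and documented everywhere randomness could
  creep in: gene id in rankings, label order in votes, first label on a
  zero decision, smallest $k$ at an accuracy maximum.
* **SMO step acceptance** uses a relative threshold of $10^{-10}$ on the
  $\alpha_2$ move; the dual objective is evaluated at both clip ends when
  the curvature $\eta \leq 0$.
* **Degenerate inputs** are defined, not rejected: constant genes
  discretize to zeros, zero-sample regions count as zero, an absent class
  yields a constant pair predictor, empty test lists yield empty curve
  lists, an empty cohort summarizes to an empty table.
* **File formats** are plain TSV (UTF-8, `.` decimal, no quoting), genes
  as rows in matrices, annotations in a separate table — the wide-short
  shape of expression data and the way atlases ship ontology separately.
  Feature-list scores round-trip to 12 significant digits; serialized SVM
  models round-trip predictions exactly (17 significant digits).

## Known limitations

* With high-resolution test sets (hundreds of samples), IFS curves
  plateau and then fluctuate by single samples; the first-drop inflection
  rule consequently selects compact prefixes near the start of the
  plateau rather than the accuracy-maximizing set. That is the rule's
  intent — compactness over maximal accuracy — but users wanting the
  maximum should read `max_accuracy_point()` instead.
* The mutual-information estimator is the plug-in estimate; with very few
  samples per donor it is biased upward, and rankings on donors with tens
  of samples should be treated cautiously.
* The quotient-vs-difference mRMR variant and the discretization
  threshold genuinely change rankings on real data; both are parameters,
  and conclusions should be checked for stability across them.
* Runtime scales linearly in genes for ranking and roughly in
  $n_{\text{curve}} \times$ (samples$^2$ to samples$^3$) for the SMO
  stage; the compiled solver handles the published sample counts
  comfortably, but `n_curve = 500` on ~900-sample donors is an overnight
  setting, not an interactive one.
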