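---
title: "Models and methods: quantifying supercomplex association from bait-tagged pull-downs"
author: "PulldownAssoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PulldownAssoc)
```

## The experiment and its observation model

A GFP pull-down captures, per sample, the bait complex together with
whatever is physically attached to it, plus a layer of nonspecifically
bound protein. The package models the expected label-free abundance of
protein $p$ (member of complex $C$, detection efficiency $d_p$) in a
sample whose bait strain tags complex $B$ as

$$E[x_{p}] \;=\; \kappa_B\, d_p\, m_{p,B} \;+\; \nu_p,
\qquad
m_{p,B} = \begin{cases}
1 & C = B\\
f_{B\leftarrow C}\, s & C \neq B
\end{cases}$$

where $\kappa_B$ is the capture scale of the strain (how much bait was
pulled down), $f_{B\leftarrow C} = n_{BC}/N_B$ is the fraction of $B$
complexes engaged with a copy of $C$ ($n_{BC}$ supercomplexes per cell,
$N_B$ copies of $B$), $s$ is the within-supercomplex stoichiometry
(partner copies per bait copy, 1 by default), and $\nu_p$ is a
strain-independent nonspecific background rate. The GFP marker itself has
expectation $\kappa_B d_{GFP}$; in the untagged WT strain nothing is
captured, so every protein shows only $\nu_p$ and GFP is absent.
Observed values are the expectation times multiplicative log-normal
noise, $x = E\,e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$ —
label-free MS intensities are strictly positive and right-skewed, which a
Gaussian on the log scale captures with one parameter.

Because $n_{BC}$ is a property of the *pair*, the ground truth is
reciprocal by construction: $f_{B\leftarrow A} N_B = f_{A\leftarrow B}
N_A = n_{AB}$. `reciprocityCheck()` measures how far a set of estimates
drifts from this identity; on real data the two directions and external
copy-number estimates need not cohere, which is itself informative.

## The estimators and the choices behind them

**Bait normalization.** Dividing a sample by its GFP abundance makes
values comparable per captured bait copy; $\kappa_B$ and $d_{GFP}$
cancel in every downstream ratio. WT samples cannot be bait-normalized
and are passed through flagged; the volcano against WT therefore runs on
the *equal-total* scale instead, which assumes most of the detected
proteome is unchanged between runs. These two scales coexist
deliberately and are tracked by a mandatory scale tag so that each
estimator can refuse input on the wrong scale.

**Association fraction.** For bait complex $B$ and partner $A$, each
$B$-strain replicate contributes one ratio: $A$'s summed subunit
abundance in that replicate over the *mean* of $A$'s summed abundance in
its own pull-down. Two direction conventions circulate for this kind of
ratio (numerator from the partner's pull-down or from the bait's); the
package uses the form above because it is the one consistent with the
defining thought experiment — if every copy of $B$ carried one $A$, the
two abundances would match and the estimate is exactly 100 % — and with
the estimator's dimensional reading as a fraction *of B*. Replicates are
not paired by index: the pull-down runs of two strains share no
experimental pairing, so each numerator replicate is divided by the
denominator-group mean.

**Interface (one-vs-rest) test.** A subunit sitting at the
complex–complex contact is retained in foreign pull-downs more than its
complex-mates. Its per-replicate ratios (foreign value over home-pull-down
mean) are tested against the *pooled* ratios of all other eligible
subunits of the same complex in the same pull-down, with Student's
equal-variance t-test. Pooling treats the rest of the complex "as a
whole"; a per-subunit pairwise alternative would multiply comparisons
without changing the nomination logic. Candidates must also sit above the
complex's median ratio, so significantly *depleted* subunits are never
nominated. Subunits undetected in their home pull-down have an undefined
denominator and are excluded with a warning rather than imputed.

**Volcano.** Per protein and bait: $\log_2$ of the ratio of replicate
means, guarded by a pseudo-count of $10^{-6}\times$ the grand mean
(zeros are real in this data), and a t-test on the linear normalized
values. Raw p-values at the 0.05 line drive the classification;
a Benjamini–Hochberg column is emitted alongside but deliberately does
not gate the categories, matching the convention of drawing the volcano
at the unadjusted line. The boundary case $\log_2\mathrm{FC} = 0$ with
p < 0.05 has no direction and is classified not significant.

**Degenerate t-tests.** Noise-free simulated data produce groups with
exactly zero variance. The pooled t-test then resolves by convention:
equal means give $(t, p) = (0, 1)$, unequal means $(\pm\infty, 0)$. This
keeps noise-free pipelines runnable end to end.

## Simulator defaults

The generator's defaults describe the study conditions the package is
built around: five strains (PSI, PSII, CYTB6F, ATPASE baits + WT),
triplicates, a PSI:PSII copy ratio of 4.5, and supercomplex counts
yielding 9.9 % of PSII engaged with PSI, 4.1 % and 2.0 % of Cyt b6f
engaged with PSI and PSII, and small ATP-synthase and PSI–NDH-1
fractions. Copy numbers for Cyt b6f (0.7) and ATP synthase (0.5) are
placeholders — no measured values were available — chosen below PSII only
so that the default capture scales ($\kappa$ = bait copy number)
reproduce the observed GFP-abundance ordering PSI > PSII > Cyt b6f >
ATPase. Detection efficiencies default to 1 (heterogeneity is a config
hook), background to 0, noise SD to 0.2 on the log scale (a typical
replicate CV for label-free protein quantification). The bundled
`study_like_config.yaml` adds a nonspecific background proteome (135
extra proteins at rate 0.05, mapped subunits at 0.002) so that a
simulated run detects 180 proteins of which 38 belong to the four
photosynthetic complexes, and plants 3× interface boosts on PsaK, PetM
and the ATP-synthase b′ subunit.

**Seeding contract.** Every cell draws its noise from a substream seeded
by a stated hash of (master seed, sample id, protein id). Adding a
protein or a sample therefore never perturbs the values of existing
cells, and identical inputs reproduce byte-identical tables — the
property the pipeline's manifest relies on.

**What the simulator does not emulate.** No peptide-level structure, no
missing-value mechanism (undetected means zero, as in dense aggregate
tables), no strain-specific stickiness (background is shared with WT),
no run-order or batch effects, and no disassembly of weak supercomplexes
during purification. Passing recovery tests on these simulations
validates the estimators *given* the observation model; on real data the
association fractions remain lower bounds wherever complexes dissociate
during solubilization and washing, and detection-efficiency differences
between subunits cancel only in the ratio estimators, not in raw complex
sums.

## AFM morphometry

Synthetic topographs are sums of isotropic Gaussian bumps (one per
particle vertex) plus i.i.d. height noise on a grid with half-integer
pixel centres. Cross-sections are sampled at pixel spacing by bilinear
interpolation, optionally averaged over perpendicular offsets. The
profile background is the median of the first and last 10 % of samples
(profile ends rest on the support — a stated convention, since the
measurement protocol leaves it open whether heights are taken above mica
or the local background); particle height is the maximum above that
background, and the vertex distance spans the first to last local
maximum with topographic prominence ≥ 0.5 nm (the scale of the reported
height SDs; configurable). Tip–sample convolution is not modelled, so
synthetic peak *widths* are not comparable to real images — heights and
peak-to-peak distances, the two reported observables, are. Reference
values for the PSI trimer (5.7 ± 0.5 nm height, 9.6 ± 0.8 nm vertex
distance, n = 21) and PSII dimer (5.6 ± 0.5 nm, 10.4 ± 1.16 nm, n = 11)
ship in `afmReference()` for comparison reporting.

## Numerical conventions and test scales

Tables are dense and zero-filled; identifiers are case-sensitive verbatim
strings; abundance round trips through CSV/TSV are exact to better than
1e-9. The estimator-exactness properties (noise-free recovery,
reciprocity) are asserted at 1e-9. The stochastic properties in the test
suite run at sizes chosen to keep the suite fast while leaving comfortable
statistical margins: 200 simulations for noise recovery (median absolute
error < 0.03 at noise SD 0.2), 10 000 null proteins for t-test
calibration (Kolmogorov–Smirnov p > 0.01, ~5 % flagged at the 0.05
line), 100 simulations for planted-interface recovery (≥ 90 %
nomination of a 3×-boosted subunit at noise SD 0.1).

## Known limitations

Association fractions inherit an upward bias from nonspecific background
(the partner's background inflates the numerator); the bias is monotone
in $\nu$ and disappears under WT subtraction, which is available but off
by default since the estimator definition does not include it. The 1:1
stoichiometry assumption scales estimates linearly ($\hat f = f s$);
violations are testable in simulation via the `s` config hook but not
identifiable from a single pull-down design. Oligomeric states (PSI
trimer, PSII dimer) are not deconvolved — all quantities are
monomer-equivalent. The interface test nominates subunits enriched in
foreign pull-downs; it cannot distinguish direct contact from indirect
retention effects (e.g. lumenal extrinsic subunits whose binding is
modulated by the association).
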