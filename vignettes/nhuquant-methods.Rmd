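---
title: "Models and methods behind nhuquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nhuquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhuquant)
```

## The assay and its model

A native holdup (nHU) experiment exposes a crude cell extract to a resin
saturated with an immobilized bait. Preys that bind the bait are retained;
everything else stays in the supernatant, which is quantified by label-free
mass spectrometry against a control resin. The fraction of a prey bound at
equilibrium — its *degree of binding* — is

$$\theta = 1 - \frac{I_\mathrm{free}}{I_\mathrm{tot}}
        = \frac{C_\mathrm{bait}}{C_\mathrm{bait} + K_\mathrm{app}},$$

a single-site hyperbola in the bait concentration with apparent
dissociation constant $K_\mathrm{app}$. Inverting it at a known (measured)
bait concentration converts a depletion into an affinity:

$$K_\mathrm{app}
  = \frac{(C_\mathrm{bait} - C_\mathrm{prey}\theta)(1-\theta)}{\theta}
  \approx \frac{C_\mathrm{bait}(1-\theta)}{\theta},$$

the approximation holding whenever the prey is far below the bait — the
normal situation for endogenous preys (nM) against a resin bait (tens of
μM). `kapp_from_theta()` implements both forms; they agree to better than
one part in $10^9$ at $C_\mathrm{prey} = 10^{-12} C_\mathrm{bait}$.

Assumptions worth keeping in mind: a single binding site, true equilibrium
at the moment of phase separation, and no kinetic information — on/off
rates and multivalent binding are out of scope.

### Degenerate inputs

Measured ratios are noisy, so $\theta$ can stray outside $(0, 1)$.
Negative $\theta$ (enrichment) is reported as-is with $K_\mathrm{app} =
\infty$ and a `non-binder` flag rather than an error, because
proteome-scale tables must survive. $\theta \ge 1$ (over-depletion) errors
by default; with `clamp = TRUE` it is clamped to $1 - 10^{-6}$, which caps
reportable affinities at $10^{-6} C_\mathrm{bait}$ — tighter binding is
not measurable at a single bait concentration anyway.

### Tethered complexes

When a complex A–B is captured through A only, both depletions are
measurable and B's is never larger. Assuming A–bait and A–B binding are
independent, the A–B link affinity is

$$K_\mathrm{app,link} =
  \frac{(C_A\theta_A - C_B\theta_B)(\theta_A - \theta_B)}{\theta_A\theta_B}.$$

`tethered_link_kapp()` exposes this generically. The estimator was
validated against a brute-force numerical solution of the full
three-species resin equilibrium (bait–A with A–B on an independent site):
in the regime the formula assumes (prey concentrations well below the
captured amounts), the generating link $K_d$ is recovered within 10%
across a grid of link strengths — see `test-holdup-core.R`. Violations of
$\theta_B \le \theta_A$ are flagged `inconsistent`, not silently used.

## The proteome-scale pipeline

`run_nhu_pipeline()` composes five stages, in the order they are applied
to real DIA output:

1. **Median normalization.** Each sample column is scaled so its median
   detected intensity equals the median of the per-column medians. The
   target makes normalization exactly idempotent; scaling to the pooled
   grand median does not (after one pass the pooled median can still
   drift, rescaling every column by a common factor), and the two differ
   only by that common factor.
2. **Imputation.** Missing values are replaced by draws, with
   replacement, from the empirical bottom decile of all detected
   intensities in the whole dataset — values "similar to the lowest 10%".
   The decile is global, not per sample, matching the description of the
   procedure being applied to the entire dataset. One seeded generator per
   pipeline run; the seed is echoed into the output metadata.
3. **Testing.** Unpaired, two-tailed, equal-variance t-tests on log2
   intensities; the fold change is the difference of mean log2
   intensities. Biological and technical replicates are pooled (N = 6 per
   condition in the emulated design). Zero-variance rows — which
   imputation can create — report the machine-minimum p with a
   `zero-variance` flag instead of erroring.
4. **Hyperbolic threshold.** Significance uses the volcano boundary
   $y(|x|) = y_0 + c/(|x| - x_0)$ for $|x| > x_0$ (infinite inside),
   boundary inclusive, with $y_0 = 1.3$ ($p = 0.05$), $c = 1$, and
   $x_0 = 2\hat\sigma$ of the fold-change distribution. As printed, the
   one-arm form $y_0 + (-c)/(x - x_0)$ only diverges correctly on one
   side; the symmetric two-arm form matches the stated meanings of $y_0$
   and $x_0$, and the side restriction (binding = depletion side) is an
   explicit argument. $\hat\sigma$ comes from a least-squares Gaussian fit
   to a Freedman–Diaconis histogram; if that fit fails, a scaled-MAD
   fallback is used and flagged. No multiple-testing correction is applied
   for classification (the curve plays that role); a Benjamini–Hochberg
   column is emitted for reference.
5. **Affinity conversion.** Depletion-side fold changes become
   $\theta = 1 - 2^{\mathrm{log2FC}}$ and then $K_\mathrm{app}$ at the
   supplied bait concentration. Enrichment-side proteins keep a negative
   $\theta$ and are excluded from conversion.

## Binding-curve fits

**Titration holdup.** $\theta(C_\mathrm{bait}) = f\,C_\mathrm{bait} /
(K_\mathrm{app} + C_\mathrm{bait})$, fitted by bounded (`port`) nonlinear
least squares, $1/\mathrm{sd}^2$ weights when replicate spreads exist,
three log-spaced $K$ starts. The *fraction of binding-capable prey* $f$
is the saturation plateau: the complete model pins $f = 1$, the partial
model floats it in $(0, 1]$. Data with no curvature (all $\theta$ within
twice the noise of zero) return a `no-binding` result with
$K_\mathrm{app} = \infty$ instead of a fit failure.

**Direct FP.** The quadratic (ligand-depletion-exact) two-species
solution gives the bound probe fraction; polarization interpolates
between $P_\mathrm{free}$ and $P_\mathrm{bound}$. All three parameters
are floated (whether the original analysis fixed $P_\mathrm{bound}$ from
a saturating control is unstated; floating it is the conservative
choice), with $P_\mathrm{free}$ initialized from the zero-receptor point.
If the bounded `nls` stalls — which happens on noisy, weakly saturating
curves — a bounded quasi-Newton fallback on $(\log_{10} K_d,
P_\mathrm{free}, P_\mathrm{bound})$ takes over. Curves whose top point
reaches less than half the fitted amplitude are flagged
`non-saturating`.

**Competitive FP.** Rather than a closed-form "competitive equation", the
exact three-species equilibrium is solved: free receptor $r$ satisfies
$r + rL/(K_L + r) + rC/(K_C + r) = R_\mathrm{tot}$, monotone in $r$ and
bracketed in $[0, R_\mathrm{tot}]$, solved to $10^{-12}$ relative
tolerance. The closed-form cubic (via `polyroot`) is kept in the test
suite as an independent oracle; both agree to $10^{-8}$. The competitor
$K_d$ is the single floated parameter, with probe $K_d$ and plateaus
frozen from the direct fit. Because the equilibrium is exact, the
IC50-vs-$K_i$ distortion of the ligand-depletion regime is handled
natively — the suite checks that a competitor identical to the probe
shows an IC50 above its $K_d$ yet fits back to the probe $K_d$. FP
model curves contain no $f$ parameter by construction: polarization only
reports the state of the fluorescent molecules, which is why FP cannot
detect partial binding and titration holdup can.

## Motif discovery and re-ranking

Short linear motifs live in intrinsically disordered regions, so scanning
is disorder-aware. A residue is disordered iff it lies outside every
annotated domain interval and (experimental disorder evidence, or
AF2-rsa > 0.582, or — only when no AF2 track exists — IUPred > 0.4)
holds; maximal runs shorter than 5 residues are cleared. The precedence
(domains first, then experiment, then predictors, with IUPred as the
AF2 fallback rather than an OR) follows the most literal reading of the
rule's "otherwise"; the OR combination is available via `combine = "or"`.

`scan_consensus()` reports all, possibly overlapping, matches of a
fixed-position pattern (`x` = wildcard) with 5 flanking residues of
context, 1-based inclusive coordinates in every report (0-based half-open
only transiently inside the scanner). Enrichment against the proteome
background counts *proteins with at least one instance* — not instances —
and supplements the fold ratio with an upper-tail hypergeometric
probability. Conservation re-ranking averages per-residue conservation
over the core positions only (flank conservation would dilute the signal
with sequence that is not under the same constraint), then orders types
by mean instance conservation with a lexicographic tie-break for
determinism.

## What the synthetic data emulate — and what they do not

`simulate_nhu_ms()` forward-models the hyperbolic law exactly: binder
bait-channel intensities are the control level times $(1-\theta)$ before
noise. Defaults state the emulated world: 1000 protein groups, 20
binders with $K_\mathrm{app}$ log-uniform in 0.5–50 μM, bait 26 μM,
6 + 6 replicates, log2 replicate noise 0.15, 5% missing-at-random plus
an extra 20% missingness for bottom-decile cells (detection-limit
behaviour), and abundances log-normal with mean 7 and sd 0.65 decades —
a realized 1000-protein span of ≈ $10^5$–$10^{9.5}$, the dynamic range
of DIA protein-group intensities. Not emulated: peptide-level roll-up,
correlated replicate structure, interference, batch effects, or
compositional distortion from strong binders. A green recovery test
therefore establishes that the statistics recover a hyperbolic world,
not that any real interactome was reproduced.

Two properties of this world matter for interpretation. First, the
tightest binders are the hardest to recover within 2-fold: at
$\theta > 0.95$ a single missing replicate imputed from the bottom decile
shifts the fold change by more than one log2 unit — imputation as a
type-II error source is intrinsic to the method, not an artifact of the
generator. Because a single draw contains only ~13 sub-10 μM binders,
the recovery acceptance test pools five seeded simulations (~65 binders)
so that the 80% property is measured above the two-binder resolution of
one draw. Second, in the motif null world (conservation effect 0) the
planted type's rank is *not* exactly uniform across types: with ~19
instances against 1 per decoy its mean has the smallest variance and its
rank concentrates mid-field; the null test asserts dispersion, not
uniformity.

The motif generator plants consensus instances inside disordered linkers
(IUPred 0.8) between domain blocks (IUPred 0.2), with planted-core
conservation shifted +0.3 above a background of 0.4 ± 0.1 (truncated to
[0, 1]). The +0.3 effect encodes the stated biology — functional motifs
are distinctly more conserved than neutral disordered background — and
gives the 14-partner / 14-decoy scale a clear separation; it was chosen
once as the stated world, not fitted to a test outcome.

## Numerical choices

* Concentrations are numeric value + unit string; `convert_conc()` is the
  only conversion point. Holdup algebra runs in the caller's unit; FP
  fitting normalizes to μM.
* Equilibrium root-finding: `uniroot` at $10^{-12}$ relative tolerance;
  competitive $K_d$ search on $\log_{10} K_d \in [-6, 5]$ with a local
  polish pass.
* Seeds: every generator takes a root seed and derives per-component
  child streams (multiplicative-congruential mix, kept below $2^{31}$),
  so adding one generator call never perturbs another's draws; caller RNG
  state is saved and restored.
* Ties in type ranking: lexicographic; ties in the result table sort:
  by `K_app`, then `prey_id`.

## Known limitations

Single-site equilibria only; no kinetics, cooperativity or multivalency.
The threshold's Gaussian fit assumes a unimodal fold-change bulk; heavily
contaminated null distributions fall back to MAD. The competitive fit
holds the direct-fit parameters fixed and so inherits their errors
without propagating them into the competitor's standard error. The
scanner supports fixed positions and wildcards, not full regular-expression
character classes.
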