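---
title: "Methods: deterministic mutation/epimutation-selection balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic mutation/epimutation-selection balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibalance)
```

## The model

`epibalance` implements a deterministic single-locus model for an
infinite, diploid, sexually reproducing population with three
(epi)allelic states: the wild-type allele A, a deleterious allele a, and
a deleterious epiallele B of the wild type (for example, an aberrant
heritable methylation state).  The deleterious allele is assumed not to
be epimutable; the wild-type allele is.  The state of the system is the
frequency vector $(p_A, p_B, p_a)$, and one generation applies five
stage operators in a fixed life-cycle order:

1. **Mating** with inbreeding coefficient $f$: each homozygote X/X forms
   at frequency $p_X^2(1-f) + p_X f$ and each unordered heterozygote X/Y
   at $2 p_X p_Y (1-f)$.  Mating never changes allele frequencies.
2. **Paramutation** on zygotes: A/B converts to B/B at rate $m_1$, and —
   only in the scenario where the deleterious allele is itself
   paramutagenic — A/a converts to B/a at rate $m_2$.  Both act
   simultaneously on the post-mating zygote pool; neither feeds the
   other within a generation.
3. **Selection**: genotype frequencies are weighted by relative
   fitnesses $w_{XY}$ and renormalized by the mean fitness $\bar w$.
4. **Gamete formation**: allele frequencies are read off as homozygote
   plus half of each heterozygote.
5. **Spontaneous epimutation** on gametes ($A \to B$ at $t_1$,
   $B \to A$ at $t_2$), then **mutation** ($A \to a$ at $u$, $a \to A$
   at $z$, $B \to a$ at $u'$).

Epimutation and mutation act on gamete (allele) frequencies after
selection; genotypes are re-formed only at the next mating.  All stages
except selection conserve total frequency by construction; a defensive
renormalization is applied only if floating-point drift exceeds
$10^{-12}$.  The map is exact and deterministic — identical inputs give
bitwise-identical outputs.

Two fitness schemes are built in.  Under *incomplete dominance*,
$w_{AA} = 1$, $w_{Aa} = 1 - hs$, $w_{aa} = 1 - s$, $w_{AB} = 1 - h_2
s_2$, $w_{BB} = 1 - s_2$, and $w_{Ba} = 1 - h_2 s_2 - h s + s_3$, where
$s_3 \ge 0$ is a compensatory interaction that can make the B/a pairing
fitter than either deleterious homozygote (plausible when a regulatory
mutation and an epimutation push expression in opposite directions).
Under *complete dominance* the wild type masks everything it pairs with
and the epiallele masks the deleterious allele:
$w_{AA} = w_{Aa} = w_{AB} = 1$, $w_{BB} = w_{Ba} = 1 - s_2$,
$w_{aa} = 1 - s$; the regime $w_{Ba} > w_{BB}$ is then unreachable.
Raw six-entry fitness tables are also accepted, which is how strict
orderings of $(w_{aa}, w_{Ba}, w_{BB})$ that the builders cannot produce
(e.g. $w_{Ba}$ smallest) are specified.

The implementation keeps the R-level stage operators as the reference
implementation and runs long iterations through an identical compiled
kernel; a property test holds the two paths together on random states.

## Parameters and defaults

| parameter | meaning | typical magnitude |
|---|---|---|
| $u$, $z$, $u'$ | mutation rates (A→a, a→A, B→a), per generation | $10^{-9}$ |
| $t_1$ | forward spontaneous epimutation rate A→B | $10^{-5}$ |
| $t_2$ | epiallele reversion rate B→A | $10^{-4}$ (stable epiallele) to $0.2$ (unstable) |
| $m_1$, $m_2$ | paramutation rates | up to order one; $m_2 = 0$ except in the paramutagenic-allele scenario |
| $f$ | inbreeding coefficient | $0$–$0.5$ |
| $s$, $s_2$ | selection against a and B | $0.01$–$0.02$ |
| $h$, $h_2$ | dominance of a and B | $0.5$ |
| $s_3$ | compensatory B/a term | $0$–$0.012$ |

All rates are probabilities per generation (dimensionless, in $[0,1]$).
The preset registry (`preset_names()`) encodes the parameter sets used
in the model's published numerical experiments; presets default to the
starting state $(0.98, 0.01, 0.01)$, a wild-type population already
segregating small amounts of both deleterious variants, and that choice
is recorded in run metadata.

## Equilibria

Iteration (`find_equilibrium()`) declares convergence when every
frequency changes by less than `tol = 1e-13` for `patience = 100`
consecutive generations, with a cap of $10^7$ generations.  The
tolerance must sit far below the smallest equilibrium frequencies of
interest — mutation-scale frequencies are of order
$u/(hs) \sim 10^{-7}$ — and the patience guards against mistaking the
slow crawl near a bifurcation for stationarity.  Near the bifurcation
scans reported below the slowest runs take a few times $10^5$
generations; everything in the test suite and the acceptance script
runs in seconds on one CPU.

Twelve first-order analytic equilibrium approximations are implemented
exactly as typeset in the model's tabulation, without algebraic
simplification, so each can be reviewed line by line (`analytic_equilibrium()`).
They are valid when the input rates are small, of order
$\zeta = \max(u, z, u', t_1)$ (including $t_2$ when the stable-epiallele
scenario is selected).  Representative closed forms: without
paramutation the balance is $\hat p_a \approx u/(hs)$ and
$\hat p_B \approx t_1/(h_2 s_2)$; with inbreeding the denominators
become $fs + hs(1-f)$ and $f s_2 + h_2 s_2 (1-f)$; with paramutation the
epiallele denominator acquires the term $m(w_{AB} - 2 w_{BB})$, so
paramutation *raises* $\hat p_B$ when $w_{AB} < 2 w_{BB}$ and *lowers*
it otherwise; with an unstable epiallele the denominator becomes
$1 - (1-t_2)\bigl(w_{AB} - m(w_{AB} - 2w_{BB})\bigr)$.

**Agreement policy.**  The first-order truncation has relative error of
order $\zeta/D$ where $D$ is the smallest selection denominator in the
formula.  Numeric-versus-analytic comparisons are therefore *asserted*
at 1% relative error only when $\zeta \le 10^{-5}$ and every denominator
is at least $10^2\,\zeta$ — exactly the factor for which the 1% bound is
guaranteed — and are reported without judgement outside that region.  A
comparison against a formula whose validity constraints fail is refused
rather than reported.

**Regime conditions.**  Each tabulated equilibrium carries printed
validity conditions (fitness orderings, rate magnitudes,
paramutation-versus-selection bounds).  Conditions written as "much less
than" are read as at least an order of magnitude apart ($10\,a < b$);
approximate inequalities ($\gtrsim$) have no exact boundary, are treated
as strict, and verdicts within 25% of the boundary are flagged as
marginal.  One transcribed upper bound for the moderate-frequency
regime under inbreeding is negative for all admissible fitness values;
it is evaluated exactly as defined, so that row's verdict is
conservative (effectively never true) and mutual-exclusivity checks are
unaffected.

**Qualitative classes.**  Equilibria are labelled per variant as
`very_low` ($<10^{-4}$), `low` ($<0.05$), `moderate` ($<0.5$) or `high`,
separating mutation-scale ($u/hs$), epimutation-scale ($t_1/h_2 s_2$)
and order-one frequencies across all regimes the model produces, plus
the identity of the leading variant (ties broken in the fixed order A,
B, a).  For censuses over discrete parameter sets
(`enumerate_equilibria()`), distinct outcomes are distinct
(label-tuple, stability) pairs.  For *continuous* sweeps along a branch
the labels necessarily change as the branch crosses the fixed
thresholds, so branch identity is the leading variant: the three
equilibria of the unstable-epiallele scenario are exactly the
wild-type-led, epiallele-led and deleterious-allele-led branches.

## Cycling

In the regime where paramutation is stronger than selection and
$w_{aa} > w_{Ba} > w_{BB}$, the frequencies spiral into the equilibrium.
Cycling is measured on the increments of $p_a$: the oscillation count is
the number of sign changes, the duration is the generation of the last
sign change, and the amplitude is the largest excursion from the final
value.  Increments smaller than the convergence tolerance carry no sign,
which prevents floating-point jitter at the fixed point from being
counted as oscillation; `detect_cycling()` exposes the threshold (`eps`)
and defaults it to zero for raw series.  Since no external definition of
"cycling duration" exists, only *orderings* of durations across
parameter values (e.g. longer cycling under stronger inbreeding) are
asserted in tests, never absolute durations.

## Stability

Local stability is assessed numerically on the reduced two-dimensional
map in $(p_a, p_B)$ (the third frequency is determined by the simplex
constraint).  The Jacobian is computed by central finite differences of
the *exact* map — not of the first-order approximation — with a
per-coordinate step $10^{-7}\max(|x_i|, 10^{-3})$, shrunk where needed
so both evaluations stay inside the simplex (some equilibria sit within
mutation-scale distance of its boundary).  A fixed point is stable when
both eigenvalue moduli are below $1 - 10^{-8}$ and unstable when either
exceeds $1 + 10^{-8}$; moduli inside that band are reported as
neutral/inconclusive, as for the identity map of the process-free null
model.  The $10^{-8}$ margin sits above the finite-difference noise
floor ($\varepsilon/h \approx 3\times 10^{-9}$ for the step above) and
far below every genuine eigenvalue gap observed in the model (the
closest stable modulus seen is about $0.9995$, at the cycling
equilibria, where the eigenvalues are complex — damped spiralling).
Halving the step changes the moduli by less than $10^{-4}$ at all
tested equilibria.

## Bifurcation scans

With an unstable epiallele ($t_2 = 0.2$) the equilibrium epiallele
frequency follows a low branch $\hat p_B \propto t_1$ until the
effective paramutation rate overcomes reversion — to leading order at
$m(1-f)(1-t_2) = t_2$, i.e. $m \approx 0.25$ at $f = 0$ and
$m \approx 1/3$ at $f = 0.25$ — beyond which an order-one branch grows
continuously.  Because the forward epimutation rate is tiny, the
transition at machine precision is a sharp *knee*, not a discontinuous
jump: below the threshold $p_B$ is of order $t_1/D(m)$ with
$D(m) \to 0$, above it $p_B$ grows linearly in $m$ and independently of
$t_1$.  `find_critical_m()` bisects on the equilibrium $p_B$ (computed
from the full grid of starts) and assigns each trial point to the branch
it resembles *on the log scale*, since the two branches live on
different orders of magnitude; this makes the bisection converge to the
knee — the termination point of the low branch — rather than to an
arbitrary mid-crossing of the statistic.  For the fitness pairing with
$w_{BB} = 0.99 > w_{aa}$ the knee sits at $m \approx 0.259$ (the exact
singularity of the low-branch denominator is $0.2589$; the leading-order
value is $0.25$).  The bracket statistic must move by more than 0.1
between the bracket ends, otherwise a no-threshold error is raised.

## Census protocol

The equilibrium censuses instantiate $w_{AA} = 1$,
$w_{Aa} = w_{AB} = 0.995$, and all six strict orderings of
$(w_{aa}, w_{Ba}, w_{BB})$ over the value triple $(0.99, 0.985, 0.98)$ —
selection of order 1–2% as in the published experiments — crossed with
weak ($m = 0.001$, below the wild-type-high regime's bound
$m(2w_{BB}-w_{AB}) < w_{AA}-w_{AB}$) and strong ($m = 0.05$, exceeding
$w_{AA} - w_{aa}$ and $w_{AA} - w_{BB}$) paramutation, at the standard
rates $u = z = u' = 10^{-9}$, $t_1 = 10^{-5}$, $t_2 = 10^{-4}$.  Each
parameter set is iterated from four starts (near fixation of each
variant, plus the barycenter).  This yields exactly five stable classes
with random mating, five under inbreeding ($f \in \{0.1, 0.25\}$), and
four under complete dominance, where the compensatory class requiring
$w_{Ba} > w_{BB}$ cannot exist.  Multiple starts matter: in the
paramutagenic-deleterious-allele scenario the wild-type-led and
deleterious-allele-led equilibria can be simultaneously valid, and the
outcome then depends on the initial frequencies.

## Numerical choices and degenerate inputs

* Frequencies are validated to be non-negative and to sum to one within
  $10^{-12}$ at every stage boundary.
* A population with zero mean fitness raises a degenerate-population
  error; formulas whose denominators are non-positive raise an
  invalid-regime error naming the offending constraint.
* Argmax ties in classification break in the fixed order A, B, a.
* Tables are serialized with 17 significant digits so that re-reading
  reproduces the doubles bit-exactly; identical configurations reproduce
  identical output files byte for byte.

## Limitations

The model is deterministic and infinite-population: no drift, no
multiple loci, no environment-dependent epimutation, no beneficial
epialleles.  Stability is local linearization only — basins are probed
just by the four-point start grid — and classifications within
$10^{-8}$ of modulus one are deliberately left inconclusive rather than
resolved.  The analytic formulas are first-order truncations; outside
their validity regions (large rates, vanishing selection denominators)
only the full recursion is meaningful.
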