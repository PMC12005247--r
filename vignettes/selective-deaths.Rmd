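---
title: "Selective deaths, reproductive excess, and speed limits to adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective deaths, reproductive excess, and speed limits to adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selectdeaths)
```

## The accounting problem

Adaptation is paid for in deaths. When a beneficial allele sweeps through a
population, the individuals carrying the old allele must, on average, die
earlier or reproduce less than the carriers of the new one; those extra
deaths (and foregone offspring) are *selective deaths* — the subset of all
deaths that causally moves allele frequencies. A population can only afford
them out of its *reproductive excess*: the offspring it produces beyond the
minimum needed to keep the population going. `selectdeaths` implements this
accounting end to end: classical single-locus cost calculators, the speed
limits that follow from a finite death budget, a generalized life-history
formulation that works even for organisms without a well-defined generation,
the connection to traveling-wave models of asexual adaptation, and an
empirical pipeline that estimates the proportion of deaths that are
selective from genotype-by-environment cohort tables.

## Cost of selection

For a haploid sweep with selection coefficient $s$ on survival, the
population incurs $s(1-p)N$ selective deaths while the beneficial allele is
at frequency $p$ (`instantaneous_cost()`). Integrating per-capita selective
deaths along the deterministic trajectory $dp/dt = s\,p(1-p)$ gives the cost
of one substitution (`cost_per_sweep()`):

$$D \;=\; \int \frac{s(1-p)}{s\,p(1-p)}\,dp \;=\; \ln\frac{p_\mathrm{end}}{p_0}
\;\approx\; -\ln p_0 .$$

In this continuous-time parameterization $s$ cancels exactly, which is the
cleanest statement of the classical observation that the cost depends almost
only on the starting frequency. For a diploid autosomal locus with genotype
fitnesses $1$, $1-s$, $1-2s$ the per-capita rate doubles (two alleles per
individual), so $D \approx -2\ln p_0$; at $p_0=10^{-4}$ this is $18.4$.

Numerical choices: the integral is computed by adaptive quadrature in $p$
(relative tolerance $10^{-8}$) rather than by time stepping; the test suite
cross-checks it against an independent time-domain ODE integration. The
sweep is truncated at $p_\mathrm{end} = 1-p_0$ (symmetric truncation; the
neglected terms are below reporting precision). For the degenerate case of a
sweep already past $1/2$, the default endpoint is halfway to fixation, which
preserves the limit $D \to 0$ as $p_0 \to 1$. Dominance schemes other than
haploid and diploid-genic are declared in the interface but deliberately
unimplemented — the two implemented cases are the ones the headline numbers
rest on, and silently guessing a trajectory for the others would be worse
than refusing.

## Speed limits

Three spacing arguments are implemented (`haldane_spacing()`,
`nei_felsenstein_spacing()`, `haldane_original_spacing()`,
`ewens_spacing()`), all answering: how many generations $n$ must separate
sweeps so the cost stays within budget?

* Total cost $30N$ against a selection-intensity cap $I \le 0.1$ gives
  $n \ge 300$.
* A finite fecundity budget: with effective fecundity $k$ per adult
  (`effective_k()` folds fixed extrinsic mortality into $k$), the minimum
  spacing is $n = -\ln(p_0)/\ln(k)$ — 97 generations at $p_0=10^{-4}$,
  $k=1.1$ — against the intensity-based $-\ln(p_0)/0.1 = 92$. The two
  coincide exactly under $I = \ln k$, which the tests assert as an identity.
* The lead-based argument: with many concurrent sweeps, fitness variance is
  $\approx s/n$ and the best genotype present sits
  $c = $ `expected_extreme(N)` standard deviations above the mean.
  Capping the lead at 10% gives $n = s\,(c/0.1)^2$.

`expected_extreme()` evaluates the exact order-statistic expectation
$\int x\,N\phi(x)\Phi(x)^{N-1}dx$ by quadrature up to $N=10^{10}$
(log-scale tail probabilities keep it overflow-safe) and switches to a
Gumbel expansion above, with location $\Phi^{-1}(1-1/N)$ and scale
$1/(N\phi(b))$; the branches agree to a few $10^{-3}$ SD at the switch. For
$N=10^6$ the exact value is $4.86$ SD, consistent with the conventional
"about 4.9". A note on rounding: with the exact constant, $s=0.01$ and a 10%
cap give $n \approx 23.6$ rather than the conventionally quoted "around 20";
the package reports the computed value and leaves the historical rounding as
a discrepancy of the quoted constant's precision, not of the formula.
No quantitative claim in the package depends on it.

Judgment calls are left to the user where they are judgment calls: the
package reports $D(p_0)$ rather than endorsing any particular "20–30 N per
sweep" range, since that range encodes a belief about realistic starting
frequencies, not a formula.

## Life histories and reproductive excess

The general framework drops "fitness" and "generation" entirely. A
life cycle (`life_cycle()`) is an ordered list of transitions
(`transition()`), each of kind survival ($k \le 1$) or reproduction
($k > 1$ allowed), with per-genotype multipliers $k_{i,j}$ that may be
functions of stage size and frequencies for density-regulated steps
(resolved once on the baseline trajectory). Stage sizes and within-cycle
genotype frequencies propagate forward deterministically; fractional
individuals are allowed everywhere, since all quantities are expectations.

For a focal transition $j$ entered at size $N_j$, the minimum output
$N_{\min,j+1}$ is the smallest post-transition size that still regenerates
$N_j$ one full cycle later, holding all other transitions at baseline
(`solve_nmin()`). Two focal populations are supported: the *actual*
population, $N_j = N_{\min,j+1}\sum_i f_i \prod_{x\neq j} k_{i,x}$, and a
hypothetical population of the *best* genotype,
$N_j = N_{\min,j+1}\prod_{x\neq j} k_{\mathrm{best},x}$, with the best
genotype resolved per transition (this is what makes antagonistic pleiotropy
accountable: each transition has its own best, and selective deaths at
different transitions never cancel). Reproductive excess is then
$\mathrm{RE}_j = k_jN_j - N_{\min,j+1}$ (`reproductive_excess()`), the
budget for selective deaths at that transition; it may legitimately be
negative for a population that is not self-sustaining. Because each
$\mathrm{RE}_j$ already accounts for density regulation at all other
transitions, excesses at different transitions must not be added — and there
is deliberately no function that does.

The defining equation is verified literally in the tests: seeding a cycle
with $N_{\min}$ and simulating forward (`simulate_from()`) returns the focal
entry size to machine precision, in both modes.

For organisms without a fixed transition sequence, the bottleneck form
(`reproductive_excess_bottleneck()`) replaces the cycle product by an
expectation over possible transition paths between the focal transition and
the worst bottleneck, and the regeneration target by $N_\mathrm{bot}$, the
smallest population that reliably escapes extinction. $N_\mathrm{bot}$ is an
ecological input with no default; nothing in the data can supply it. With a
single path of weight one the form collapses exactly to the fixed-cycle
excess, which is asserted as an identity.

`wf_identities()` records the bridge back to textbook population genetics:
in an absolute-fitness Wright–Fisher model, selective deaths per capita are
$k_\mathrm{best}-k_\mathrm{mean}$, $N = N_{\min} k_\mathrm{best}$, and
per-capita excess is $k_\mathrm{mean} - 1/k_\mathrm{best}$.

## The traveling-wave connection

In large asexual populations many beneficial mutations segregate at once and
the fittest class leads the mean by $q$ mutations — a fitness lead $qs$.
`solve_lead()` computes $q$ from $(N, U, s)$ by solving the steady-state
condition of the multiple-mutations regime: the nose class establishes at
size $\sim 1/(qs)$ and must grow to dominance ($\sim N$) over the $q-1$
establishment intervals of length $\ln(s/U)/(qs)$, during which its
advantage decays stepwise from $(q-1)s$ to 0, giving

$$\ln(Ns) \;=\; \frac{q-1}{2}\,\ln(s/U).$$

The published transcendental condition this stands in for was not available
for verbatim transcription, so the package derives the condition above from
the same establishment–dominance argument and guards it with the regime's
asymptotics: the solution must lie within 15% of the initializer
$2\ln(Ns)/\ln(s/U)$ when $\ln(Ns) \gg 1$ (at the default parameters
$N=10^6$, $U=10^{-3}$, $s=0.01$: $q = 9.0$ against $8.0$) and all outputs
must be monotone in $N$, $U$ and $s$; both guards are enforced in the test
suite. The solver is bracketed (expanding bracket around the initializer)
rather than Newton, for robustness near the regime boundary, and warns
outside $s/U \ge 3$ where the model's assumptions degrade. No numerical
acceptance claim depends on the solved $q$.

Two results follow directly from the lead: the minimum reproductive excess
the best genotype needs to sustain the wave is $qs$, and the proportion of
deaths that are selective is $1 - 1/(1+qs)$ (`proportion_selective()`). The
historical 10% excess cap thus corresponds to about 9.1% of deaths
selective. `sweep_rate()` adds the de novo substitution rate
$2s\ln(Ns)/\ln^2(s/U)$.

## The empirical pipeline

`run_all()` chains the per-environment analysis of a cohort table (one row
per genotype × environment × pot, with counts at each life stage; see
`read_cohort_csv()` for the format and the column-mapping loader for foreign
layouts):

1. **Survival estimation** (`estimate_survival()`): counts are pooled across
   pots — sums of numerators and denominators, the minimum-variance binomial
   estimator for equal-design replicates. The scored transition depends on
   the planting design: seed→adult at high density (30 seeds per pot),
   seedling→adult at low density (denominator is the retained seedlings, so
   seed-stage deaths are excluded there by design).
2. **Proportion of deaths selective**
   (`proportion_selective_deaths()`):
   $\sum_i d_i(r_\mathrm{best}-r_i)\,/\,\sum_i d_i(1-r_i)$. Zero total
   deaths make the quantity undefined (`NA`), never silently zero.
3. **Winner's-curse adjustment** (`adjust_extreme_value()`): the maximum of
   hundreds of noisy rates overstates the true best genotype. The default
   strategy first runs a pooled-binomial homogeneity pretest; if the
   genotypes are indistinguishable the simulated truth is flat at the pooled
   mean. Otherwise the among-genotype variance is deconvolved by moments
   (observed minus binomial sampling variance) and the profile linearly
   shrunk to match. A parametric bootstrap from that shrunken profile yields
   the inflation $E[\max \hat r^*] - \max r^*_\mathrm{truth}$, subtracted
   from the observed maximum. Bootstrapping from the raw estimates instead
   would bake the curse into the simulated truth and undercorrect badly —
   under a shared true rate it leaves most of the bias in place — which is
   why the deconvolution step exists and why no floor at the second-best
   observed rate is applied (such a floor would pin the adjusted maximum
   near the top of the winner's-curse cloud and defeat the null-centering
   property). The adjusted proportion is returned *signed* so that its
   null-centering is a testable property; `run_all()` clamps it to
   `[0, raw]` for reporting. The `method` argument names the strategy slot
   where an alternative correction can be registered.
4. **Fecundity gate** (`fecundity_gate()`): among-genotype differences in
   per-survivor seed set are tested by freely permuting genotype labels
   across pots (pot-weighted among-genotype variance statistic). Fecundity
   selective deaths $N_i(b_\mathrm{best}-b_i)$ are charged only when the
   differences are significant; otherwise they are set to zero, the
   appropriate null for designs where fecundity differences are
   indistinguishable from noise.
5. **Reproductive excess** (`empirical_reproductive_excess()`): the
   environment's observed cycle — adults set seeds, seeds survive dispersal,
   dispersed seeds establish as seedlings, seedlings survive selectively to
   adulthood — is assembled as a `life_cycle()` and the generic best-mode
   `reproductive_excess()` is applied to the seed and seedling transitions,
   normalized per pot. Dispersal survival is unobservable in a pot
   experiment, so the seed excess is reported over an assumed range
   (default 0.1–1, a 10-fold span); the seedling excess is independent of it
   and is structurally capped by the planting design (at most 1 per
   low-density pot, 30 per high-density pot). Genotypes with zero survivors
   are omitted from the cycle's survival multipliers (they would need
   $k=0$); they still contribute to every pooled count.

All randomness flows from one master seed via deterministic child seeds, so
a rerun is byte-identical.

## The synthetic generator

`generate_cohort()` emulates the study design the pipeline targets — 517
homozygous genotypes, 2 sites × 2 water levels × 2 densities, 30 seeds per
high-density pot, ~10 sown and 1 retained per low-density pot, five
replicate pots per genotype and environment (with a single pot the
low-density transition would have a one-seedling denominator and carry no
information) — with known truth: genotype seedling→adult survival drawn from a per-water Beta prior,
shared germination (0.8), binomial survival, and gamma-mixed (negative
binomial) seed counts whose default dispersion gives a per-survivor CV near
0.5, a plausible figure for plants and pure test scaffolding rather than an
empirical claim. The default priors — Beta(30, 10) under high water,
Beta(2, 3) under low water — were chosen once so the generated truth
reproduces the qualitative field observation the pipeline is meant to
detect: within a density class, water stress both lowers mean survival and
spreads genotypes apart, so a larger share of deaths is selective in
low-water environments, and well above the historical 10% cap everywhere.
The generator writes both the pipeline's CSV input and a JSON truth sidecar
(`sd_cli("simulate", ...)`).

What the generator does *not* emulate: genotype effects correlated across
environments, pot-level microenvironment, spatial dispersal, or real
*A. thaliana* genetics. Passing the pipeline's recovery tests on synthetic
data therefore shows the estimator is consistent for the model it assumes,
not that real cohort data meet those assumptions.

## What the tests can and cannot certify

Two properties of the adjustment are statistically delicate, and the test
suite states them the only way they can honestly be stated:

* Under a shared true rate (517 genotypes × 30 seeds), the *mean* adjusted
  proportion across replicate datasets is within two standard errors of
  zero. Any single dataset scatters around zero with an SD near 0.1.
* On full-scale synthetic data, the adjusted estimator recovers the true
  proportion selective to within ±0.03 — as a mean of the signed error
  across the high-density environments of replicate studies. A
  per-environment guarantee at that tolerance is unattainable in principle:
  the best genotype's own rate estimate carries binomial noise of SD
  0.02–0.03, amplified by $1/(1-\bar r)$ in benign environments, giving
  irreducible per-environment error SDs of 0.04–0.12 even for an oracle
  estimator.

Problem sizes used by the suite were chosen to make these averages
informative: 20 replicate null datasets with $B=1000$ bootstrap replicates;
six replicate recovery studies at the full 517-genotype design with 5
high-density pots per genotype; five replicate 50-pot studies for the
consistency check. Smaller-scale variants of the same properties run in the
unit tests.

## Known limitations

* The lead condition is a derivation faithful to the multiple-mutations
  regime's argument, not a verbatim transcription of the published
  transcendental equation; its guards are the asymptotic band and
  monotonicity, and nothing quantitative is claimed beyond them.
* There is deliberately no multi-transition speed limit: once selection acts
  at more than one transition, the answer depends on the details of density
  regulation, and no general formula exists. The package computes
  per-transition excesses and refuses to combine them.
* The winner's-curse strategy assumes binomial sampling within genotype;
  pot-level overdispersion would call for a beta-binomial variant behind the
  same `method` interface.
* Deposited field datasets can be loaded through the column-mapping reader,
  but no network access or external data is required (or used) by any test.
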