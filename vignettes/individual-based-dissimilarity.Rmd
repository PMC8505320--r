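---
title: "Individual-based temporal beta-diversity: models, indices and the persistence null model"
author: "indivBeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-based temporal beta-diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indivBeta)
```

## The problem

Repeated censuses of the same plot track not just species counts but
*individuals*: a marked tree is either persisting, dead, or newly recruited
at each census. Conventional temporal beta-diversity (Sørensen, Bray–Curtis)
sees only the species-abundance margins, so it cannot separate two very
different dynamics that produce the same compositional change: slow
communities where most individuals persist, and churning communities where
high individual turnover happens to leave composition similar. `indivBeta`
implements dissimilarity indices defined directly on tracked individuals,
their multiple-unit (whole-series) extensions via the inclusion–exclusion
principle, and a randomization null model for the pattern of individual
persistence.

## Data model

A `Census` is a 0/1 occupancy matrix with one row per individual and one
ordered column per census, plus a species label per individual. Entry 1
means "alive and counted at that census". The package assumes:

* **Closed identity**: an individual id refers to the same organism at every
  census. Species labels are taken from the first appearance; later
  conflicting labels are treated as re-identifications and overridden with a
  warning (long-running plots routinely correct determinations).
* **Contiguous lifespans**: an individual present, then absent, then present
  again (a `1...0...1` pattern) is a census miss, not a resurrection. The
  gap policy makes the choice explicit: `strict` (default) refuses gapped
  data, `fill` assumes the individual was alive through internal gaps,
  `events` leaves the vector untouched but is refused by the null model.
  `strict` is the default because silent gaps corrupt the mortality and
  recruitment flows that the null model conserves: a gap would count one
  extra death *and* one extra recruit, and simulated series would then
  disagree with the observed number of distinct individuals. This
  three-way taxonomy is the package's own design; individual-tracking data
  sets differ in how misses are recorded and no single repair is right for
  all of them.

All components are computed in exact integer arithmetic and converted to
ratios only at output time, so algebraic identities between components hold
bit-exactly and the brute-force audits can require exact equality.

## Pairwise indices

For two censuses $j$ (earlier) and $k$ (later), with $x_{ij}$ the abundance
of species $i$ and $z_{oj} \in \{0,1\}$ the occupancy of individual $o$:

* species scale: $a$ shared species, $b$ unique to $j$, $c$ unique to $k$;
  $d_{sor} = (b+c)/(2a+b+c)$;
* abundance scale: $A = \sum_i \min(x_{ij}, x_{ik})$, $B$, $C$ the one-sided
  excesses; $d_{BC} = (B+C)/(2A+B+C)$;
* individual scale: $P$ persisting, $M$ dying, $R$ recruited individuals;
  $d_{MR} = (M+R)/(2P+M+R)$, the rate of individual turnover.

Mortality and recruitment split into conspecific replacement
($E_{loss} = M - B = R - C = E_{gain}$), which leaves composition unchanged,
and compositional shift ($B$, $C$). The ratio
$v_s = (B+C)/(M+R) = d_{BC}/d_{MR}$ is the fraction of individual turnover
that actually shifts composition: 0 for a perfect dynamic equilibrium
(every death replaced by a conspecific), 1 when every death and recruitment
changes composition. The identities $A = P + E$ and $B + C = M + R - 2E$
are enforced by the `PairwiseComponents` validity method and checked
property-style on random censuses; they imply $d_{BC} \le d_{MR}$, so
$v_s \in [0,1]$ wherever defined.

Zero denominators (two empty units; no turnover at all for $v_s$) are not
errors: the indices return `NA` tagged with a reason (`indexReason()`), and
batch tables carry the count of undefined entries, because a plot-level
summary that silently coerces 0/0 to 0 would bias multi-plot comparisons.

## Multiple-unit indices

The mean of pairwise dissimilarities over a series understates overall
variability because species or individuals shared by three or more censuses
are re-counted in every pair. The multiple-unit components fix this with
the inclusion–exclusion principle. The package computes the shared
components by their closed forms

$$a_{mu} = \sum_j S_j - S_T, \qquad
  A_{mu} = T_{AB} - \sum_i \max_j x_{ij}, \qquad
  P_{mu} = \sum_j I_j - I_T,$$

(per-unit totals minus pooled totals) and the loss/gain components as sums
over unit pairs of the smaller/larger one-sided exclusives, e.g.
$M_{mu} = \sum_{j<k} \min(q_{jk}, q_{kj})$ with $q_{jk}$ the number of
individuals present at $j$ and absent at $k$. The indices then mirror the
pairwise forms, e.g.

$$d_{MR.mu} = \frac{M_{mu} + R_{mu}}{2P_{mu} + M_{mu} + R_{mu}}, \qquad
  v_{s.mu} = d_{BC.mu} / d_{MR.mu}.$$

`bruteForceShared()` recomputes $a_{mu}$, $A_{mu}$ and $P_{mu}$ directly
from the alternating sum over all $2^T$ unit subsets. It is public (not
test-only) so any census can be audited, but refuses more than 10 units by
default. The suite requires exact integer agreement between the closed
forms and the enumeration on 1000 random censuses, and exact reduction to
the pairwise indices at $T = 2$.

A worked pair of two-individual censuses shows why the individual scale
matters:

```{r worked}
ex <- persistenceExamples()
occupancy(ex$longLived)
occupancy(ex$shortLived)
dMRMu(ex$longLived)    # 1/3
dMRMu(ex$shortLived)   # 7/13
```

Both series have one recruitment and one death at identical intervals —
identical `intervalFlows()` — yet the index separates them because the
long-lived founder is shared by all unit pairs ($M_{mu} = 0$) while the
short-lived configuration shares less ($M_{mu} = 2$, $R_{mu} = 5$). The
pairwise means also differ here (1/6 vs 1/2); the package computes both and
asserts nothing about their equality, since for other configurations they
can coincide while the multiple-unit index still differs.

On every shipped example and simulated census we check, the multiple-unit
index is at least the mean pairwise value. We assert this on fixtures and
simulator output only — we do not claim it as a theorem for the
individual-based indices — and the property test would surface any
counterexample rather than ignore it.

## The persistence null model

The null hypothesis is ecological drift in *who* dies: per-interval death
counts $D_t$ and recruitment counts $R_t$ are demographic facts to be
conserved, but under drift the dying individuals are an unbiased random
draw from those alive. `randomizeOnce()` therefore starts with $I_0$
anonymous individuals and, at each interval, kills $D_t$ uniformly at
random without replacement, then adds $R_t$ brand-new recruits — recruits
are themselves at risk later. Every replicate reproduces the per-unit alive
counts $I_t$ exactly, hence also $P_{mu} = \sum I_j - I_T$ (verified
internally on every replicate); only the cross-interval sharing components
$M_{mu}$, $R_{mu}$ vary.

`pSesAll()` summarizes the deviation of the observed census as a
standardized effect size

$$\mathrm{SES} = \frac{d_{MR.mu}^{obs} - \overline{d_{MR.mu}^{null}}}
                      {\mathrm{sd}(d_{MR.mu}^{null})}$$

with the *sample* standard deviation ($n-1$ denominator) over `nRand`
replicates (default 100; raise it when the SES itself is the quantity of
interest, since its noise scales as $1/\sqrt{2\,n_{rand}}$).

**Sign convention.** With the literal definition above, a community whose
individuals live *longer* than drift predicts has a *lower* observed
$d_{MR.mu}$ than the null mean — the worked pair makes this concrete: the
long-lived case (1/3) sits below the two-outcome null mean (17/39), so its
SES is negative. Some users prefer the opposite reading ("larger = more
persistent"); the `signConvention = "reversed"` option negates the value
for them. The package default is the literal definition, and the direction
is stated in every output rather than guessed.

For the worked pair's flows the null is exhaustively enumerable: the single
death either hits the founder or the recruit, each with probability 1/2, so
the null distribution is exactly $\{1/3,\ 7/13\}$, the mean is $17/39$, and
the Monte-Carlo null mean at `nRand = 2000` must land within 0.01 of it —
one of the suite's checks.

With only two censuses the index is fully determined by the flows, the null
distribution is degenerate, and the SES is reported as tagged-undefined;
three or more censuses are required for a meaningful SES.

## The census simulator

`simulateCensus()` generates individual-tracked series for calibration,
power analysis and fixtures. It emulates multi-census forest-plot data: a
fixed census schedule, exact per-interval death and recruitment counts,
contiguous lifespans, and species drawn from a skewed abundance
distribution. Defaults, chosen once as the package's study conditions:

* `nUnits = 8`, matching a typical long-running plot series;
* `nInitial = 200` individuals, the order of a 20 m × 20 m tropical-forest
  quadrat's stem count;
* `deaths = recruits = 20` per interval — ten percent turnover, a realistic
  inter-census rate for trees over ~5-year intervals;
* `nSpecies = 40` with ranked-geometric initial abundances
  (`abundanceParam = 0.15`), a strongly skewed, log-series-like community;
* recruits draw species proportionally to current abundance (drift-like);
  uniform and mixture rules are available;
* `mortalityBias = 0`: uniform random death.

With `mortalityBias = 0` the simulator *is* the generative process of the
null model, so the SES is calibrated by construction; the suite verifies
that across 100 simulated censuses the mean SES lies within three standard
errors of 0. `mortalityBias = β > 0` makes death probability proportional
to $(\text{age}+1)^{-β}$ — the minimal one-parameter family spanning drift
($β = 0$) to strong old-individual protection; at $β = 3$ a seven-interval
founder is ~500 times less likely to die than a fresh recruit, and the
observed index falls below the null mean in at least 95 of 100 simulated
censuses (the suite's sensitivity check).

What the simulator does **not** emulate: spatial structure and dispersal,
size- or species-dependent demography (beyond the age-bias family),
immigration of new species over time, observation error, and variable
census effort. Passing calibration on simulated drift therefore shows the
SES machinery is unbiased under its own null, not that real forest data
satisfy the null's assumptions.

## Numerical and design choices

* **Exact integers throughout**: components are integers; indices are
  formed as a single division at output. The `--fractions` CLI option (and
  `batchIndices(fractions = TRUE)`) serializes indices as unreduced
  `numerator/denominator` strings for bit-exact regression comparisons.
* **Problem sizes in the verification suite** (the package's own choice of
  desk-scale conditions): oracle and algebra checks use 1000 random
  censuses with $T \le 6$, at most 30 individuals and 6 species — small
  enough for $2^T$ enumeration, large enough to hit every component
  configuration; the calibration and sensitivity checks use 100 simulated
  censuses at the simulator defaults with `nRand = 100`; conservation is
  checked on 1000 replicates of each of 20 random censuses; dominance over
  the pairwise mean on 500 simulated censuses.
* **Degenerate inputs**: empty unit pairs and zero-turnover series give
  tagged-undefined values, never exceptions, in batch mode; a batch
  continues past malformed plots and reports them in the `note` column.
* **Ties and order**: unit order is declared (numeric, date, or explicit),
  pairs are always taken $j < k$ in that order, and swapping a pair swaps
  $M$ and $R$ without changing any index.
* **Seeds**: every stochastic entry point takes an explicit seed;
  `batchNullModel()` derives per-plot seeds (`seed`, `seed + 1`, ...) so
  batches are reproducible while plots stay independent.

## Limitations

* Individuals are atomic: no stem counts, biomass or size weighting, and
  no partitioning of the multiple-unit dissimilarity into
  turnover/nestedness families.
* The null model conserves flows at the whole-plot level; it does not
  constrain deaths within species, so it tests individual persistence, not
  species-level demographic structure.
* The SES sign question above is a genuine ambiguity in how practitioners
  read "deviation in persistence"; we expose both conventions instead of
  resolving it silently.
* Whether the multiple-unit index always dominates the mean pairwise value
  for the individual-based family is, to our knowledge, open; the package
  treats it as an empirical regularity and tests it only on generated data.
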