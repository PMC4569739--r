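---
title: "Recurrent mobility, returners and explorers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent mobility, returners and explorers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retex)
```

## The problem

Individual mobility traces — the time-ordered list of cell towers from
which a phone user places calls, or the census cells where a tracked
vehicle stops — show a puzzling coexistence of heterogeneity (characteristic
travelled distances spanning orders of magnitude) and predictability
(most time is spent in a handful of places). `retex` implements the
analysis toolkit built around one way of resolving that puzzle: comparing
each individual's *overall* mobility with their *recurrent* mobility, and
splitting the population into **returners**, whose travelled range is
carried by a few favourite locations, and **explorers**, whose range is
not reducible to any small set of places.

## Measures

For an individual who visits locations $i$ with weights $n_i$ (visit
counts by default, or total dwell time), total weight $N=\sum_i n_i$ and
positions $\mathbf r_i$, the total radius of gyration is

$$ r_g = \sqrt{\frac 1N \sum_{i\in L} n_i\,
   \lvert \mathbf r_i - \mathbf r_{cm} \rvert^2 },
   \qquad \mathbf r_{cm} = \frac 1N \sum_i n_i \mathbf r_i . $$

The *k*-radius $r_g^{(k)}$ applies the same formula to the $k$ most
frequented locations only, with their own centre of mass and weight sum
$N_k$; for $k$ at or past the number of visited locations it equals $r_g$
exactly. The recurrence ratio $s_k = r_g^{(k)}/r_g$ is the quantity of
interest: $s_k \approx 1$ means the top-$k$ locations carry the whole
mobility range, $s_k \approx 0$ means they do not. $s_k$ can exceed 1 for
the few individuals whose top-$k$ locations lie farther from the centre
of mass than the rest.

Ranking ties are broken by earlier first visit, then lexicographic
location id — deterministic and data independent. Individuals visiting a
single location have $r_g = 0$ and are excluded from every $s_k$
analysis, mirroring the usual CDR filter that keeps users with more than
two locations. Under dwell weighting the last visit has no onward
interval; it receives the mean of the preceding dwells so that every
visited location keeps positive weight.

**Coordinates and units.** Distances are always km, areas km². Planar
coordinates are taken as km directly. Geographic coordinates use the
haversine distance on a sphere of radius 6371.0087714 km for pairwise
distances, and an equirectangular projection about the weighted mean
lon/lat for centre-of-mass work — at country scale (a few hundred km)
the projection error is far below the tower-position noise. "Area
covered" is the convex hull of the visited coordinates: the natural
parameter-free choice, though it overestimates the activity space of
L-shaped trajectories.

## Classification

The **bisector rule** labels an individual a $k$-returner when
$s_k \ge 0.5$, i.e. $2 r_g^{(k)} \ge r_g$, and a $k$-explorer otherwise.
The tie ($s_k = 0.5$ exactly) goes to the returner side; the choice is
arbitrary but fixed, and ties have measure zero in continuous data. The
**EM alternative** fits a two-component Gaussian mixture to the
population's $s_k$ values; the higher-mean component is the returner
class. Initialisation is deterministic (means at the 25th/75th
percentiles, equal weights, common variance), so results are exactly
reproducible without a seed. We run EM on the scalar $s_k$ rather than on
the $(r_g, r_g^{(k)})$ plane: per individual the two presentations are
monotonically related, and the scalar version needs no scale
harmonisation between axes. On well-separated populations the two
methods agree on essentially every individual, which is the point: the
dichotomy is a property of the data, not of the classifier.

The **balance point** is the smallest $k$ at which returners reach half
the classifiable population; a linearly interpolated crossing is
reported alongside for populations whose fraction jumps over 0.5. On
empirical CDR populations the balance sits at $k \approx 4$.

## Heavy-tail fitting

Radius and jump-length distributions are fitted with the truncated power
law

$$ P(r) \propto (r + r_0)^{-\alpha}\, e^{-r/r_{cut}}, $$

normalised over $[r_{min}, \infty)$ by adaptive quadrature (no closed
form exists for the shifted, truncated family). Estimation is continuous
maximum likelihood over $(r_0, \alpha, r_{cut})$ — the binned
least-squares alternative wastes information and depends on the binning —
with four deterministic starts and box constraints on the log scale. Two
numerical points matter:

* the kernel is rescaled by its value at $r_{min}$ before quadrature;
  with extreme parameters the raw kernel underflows the quadrature
  routine's absolute-tolerance stopping rule and silently loses several
  percent of the normalisation constant, which corrupts the likelihood;
* $(\alpha, r_0)$ form a likelihood ridge near the exponential limit —
  a large $\alpha$ with a large shift mimics a pure exponential — so
  among starts whose likelihood agrees within $10^{-6}$ per observation
  the most parsimonious (smallest $\alpha$) solution is returned. Pure
  exponential data therefore comes back with $\hat\alpha \approx 0$
  instead of a spurious ridge solution.

Sampling uses inverse-CDF interpolation on 4,096 log-spaced knots with a
cumulative-trapezoid CDF; the grid reaches $60\,r_{cut}$, leaving
$\sim e^{-60}$ of unrepresented tail mass. `r_min` defaults to the
smallest positive observation.

## The EPR and d-EPR models

An **EPR** (exploration and preferential return) agent that has visited
$S$ distinct locations explores a new one with probability
$\rho S^{-\gamma}$ ($\rho = 0.6$, $\gamma = 0.21$) and otherwise returns
to a previously visited location with probability proportional to its
visit frequency. Preferential return is implemented by picking a
uniformly random *past visit* — exactly frequency-proportional in O(1).
Exploration jumps a distance drawn from the canonical displacement law
$(\Delta r + 1.5\,\mathrm{km})^{-1.75} e^{-\Delta r / r_{cut}}$ in a
uniformly random direction. We set the default jump cutoff at
$10^4$ km, i.e. effectively none: the defining property of the
free-space model — and the reason it fails to reproduce the empirical
returner/explorer split — is precisely that agents can travel
arbitrarily large distances, each long jump inflating $r_g$ without
touching $r_g^{(k)}$. Reinstating the empirical 80–400 km cutoff of
measured displacement distributions would smuggle the geographic
confinement back in through the jump law and erase the regime the model
is meant to exhibit (the balance point collapses from tens of locations
to below ten). Waiting times follow
$\Delta t^{-1.8} e^{-\Delta t/17\,\mathrm h}$ with a lower bound of
0.2 h (the law diverges at zero; 12 minutes is a short inter-call gap).
Waiting times only matter for dwell-weighted profiles; all $k$-statistics
are computed on event counts.

The **d-EPR** variant replaces free-space exploration with a gravity
choice over a fixed landscape: from current location $i$ a never-visited
location $j$ is drawn with probability proportional to
$\mathrm{relevance}_j / d(i,j)^2$ (the origin mass cancels in the
per-origin normalisation; the deterrence exponent is configurable).
Agents start at locations sampled proportionally to relevance and can
never leave the landscape — confinement is structural, not parametric.
When an agent has exhausted the landscape, exploration draws fall back
to preferential returns and are counted (`forced_returns`).

**Model contrast.** With matched agents and event counts the d-EPR
population reaches returner/explorer balance at a far smaller $k$ than
free-space EPR. At the sizes used in our checks (2,000 EPR agents, 600
d-EPR agents on a 10,000-location landscape, 2,200 events per agent —
a three-month observation window at about one call per hour, the regime
CDR user-selection thresholds imply) the EPR balance sits near
$k \approx 40$ and the d-EPR balance near $k \approx 4{-}5$, an
order-of-magnitude separation. Empirical reports for comparable
simulations place the two near 60 and 9; both numbers are sensitive to
the per-agent event count (EPR) and to the spatial realism of the
landscape (d-EPR — a uniform random scatter with Zipf relevances has no
clustered cities), so the robust, implementation-independent statement
is the contrast, not either absolute value. That is why the spreading
and classification checks in this package are comparative wherever
possible.

## Spreading: the global invasion threshold

The global mobility network connects two locations when at least one
trip (consecutive distinct visits in one trajectory) was observed
between them. For a metapopulation with uncorrelated degrees,
homogeneous per-capita travel rate $p$, subpopulation size $\bar N$,
recovery rate $\mu$ and reproductive number $R_0$ just above 1, the
branching-process invasion threshold is

$$ R_* \;=\; \frac{\langle k^2\rangle - \langle k\rangle}
   {\langle k\rangle^2}\; \frac{2 (R_0-1)^2}{R_0^2}\;
   \frac{p \bar N}{\mu}, $$

with invasion possible only for $R_* > 1$. The degree-moment prefactor
is isolated in one internal function so an alternative convention is a
one-line change; defaults ($R_0 = 1.1$, $\mu = 0.2$/day, $p = 10^{-3}$,
$\bar N = 10^4$) target the large-subpopulation, near-threshold regime.
Degrees are topological (trip counts are kept but do not enter $R_*$).
Because the constant prefactor conventions vary across the literature,
every check on this module is comparative — heterogeneity monotonicity,
scaling in $p\bar N/\mu$, and the mixed-population experiment — never a
target on an absolute $R_*$.

The mixed-population experiment samples populations at explorer
fractions 0–100%, builds one network per sample and summarises $R_*$
per fraction. Explorer-rich populations produce more heterogeneous
degree distributions (their trajectories touch more, and more scattered,
locations), so the mean threshold rises monotonically with the explorer
share. We use 1,000 individuals per network and 100 networks per
fraction: the paper-scale 10,000-individual samples cannot vary the
class mix against a 5,000 + 5,000 archetype pool without replacement,
and the monotonicity statement is insensitive to the sample size.

## Social ties: homophily of mobility classes

For each caller the $n$-th best friend is the $n$-th most called
contact (ties: more reciprocal calls, then id). Observed fractions
$RR, RE, ER, EE$ are computed over caller/friend pairs in which both are
classified; pairs with an unclassifiable member are excluded from the
observed and the null statistics symmetrically. The null permutes the
friend-assignment vector across individuals — the most literal reading
of "randomly reassigning best friends" — preserving the multiset of
named friends and hence the class marginals; a uniform-redraw null would
additionally destroy the friend-popularity distribution. One-sided
empirical p-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, which is valid
(sub-uniform under the null) by construction.

## Synthetic data: what it emulates and what it does not

All fixtures are planar (a tiny hand-made lon/lat fixture exercises the
geographic path separately), removing projection noise from recovery
tests.

* **Landscapes**: uniform scatter over a square, relevances following a
  Zipf rank law (exponent 1 by default — the canonical city/tower-size
  exponent). Real landscapes are clustered into cities; the uniform
  scatter underestimates the spatial correlation of relevance, which is
  the main reason absolute d-EPR balance points should not be compared
  against empirical values.
* **Archetypes**: returners get two dominant locations (58/42 split of
  an 80% top-2 share) separated by twice the target radius with tight
  satellite clusters around each; explorers get a co-located top-2 pair
  near the centre and far low-frequency satellites at
  $r_g/\sqrt{1-\text{top2\_share}}$, so the target radius is carried by
  rarely visited places. Per-individual target radii are drawn from a
  heavy-tailed law with the shape measured on CDR radii
  ($r_0 = 5.5$, $\alpha = 1.6$, $r_{cut} = 250$ km). Visit sequences
  are i.i.d. multinomial; real visit sequences have temporal order
  (home–work alternation, bursts) that the generator does not emulate,
  so passing recovery tests demonstrate geometric separability, not
  realistic temporal structure.
* **Call graphs**: each caller's ranked contacts are drawn same-class
  with probability $\pi$ and uniformly otherwise, call counts strictly
  decreasing in rank. $\pi = 0$ gives exact exchangeability (the
  type-I calibration case); $\pi = 1$ gives $RR = EE = 1$.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bitwise
reproducible. The standard checks run at: 2,000 EPR agents and 600
d-EPR agents × 2,200 events; 1,000 random profiles against brute-force
oracles; $n = 50{,}000$ for heavy-tail recovery; 11 explorer fractions
× 100 networks × 1,000 individuals for the spreading experiment; 200
null datasets for permutation-test calibration. On one CPU the full
suite runs in a few minutes.

## Known limitations

* Absolute balance points of both models depend on conditions the
  empirical literature leaves under-specified (per-agent event counts,
  landscape geometry); the package treats them as comparative
  diagnostics.
* The invasion threshold uses one (Colizza–Vespignani homogeneous
  diffusion) prefactor convention; absolute $R_*$ values are not
  comparable across conventions.
* No map matching, stop detection or tower-assignment preprocessing:
  inputs are already-discretised visit sequences.
* The convex hull "area covered" and the equirectangular projection are
  country-scale approximations; neither is suitable for continental or
  polar data.
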