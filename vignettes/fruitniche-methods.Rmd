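---
title: "Methods: habitat selection and fruit preference scoring for sympatric frugivores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat selection and fruit preference scoring for sympatric frugivores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitniche)
```

## The problem

Western lowland gorillas and central chimpanzees live side by side in many
Central African forests, eat largely overlapping sets of fruits, and build
nightly nests whose locations can be surveyed along transects. `fruitniche`
implements a quantitative pipeline for asking how two such frugivores
partition a shared landscape: which habitats each species selects for
nesting, which fruits each prefers, which fruits serve as fallback foods when
community-wide fruit availability is low, and how plants bearing those
consumption roles are distributed across habitat types.

The package works from six tabular field inputs (see `?survey_dataset`):
habitat availability points recorded every 50 m along transects, fresh nest
records, fecal samples with per-taxon seed counts, monthly phenology scores
on marked individual plants, botanical plot inventories, and a fruit trait
table (mean fruit weight, mean seeds per fruit). A seeded generator
(`generate_dataset()`) emulates all six tables with known ground truth, so
every stage of the pipeline can be exercised and validated end to end.

## Habitat selection

Nest surveys are treated at the population level (no individual
identification), with availability estimated from the transect stations. For
habitat $i$ among $m$ types, with $r_i$ the proportion of nests and $p_i$ the
proportion of availability,

$$W_i = \frac{r_i/p_i}{\sum_{k=1}^m r_k/p_k}, \qquad W'_i = m\,W_i .$$

$W_i$ sums to one across habitats; $W'_i$ compares against 1, the value under
proportional use. A Pearson chi-squared goodness-of-fit test of the nest
counts against availability gates all per-habitat calls: when it is not
significant, every habitat is reported as used proportionally. Otherwise a
habitat is preferred when the lower bound of its Bonferroni-adjusted
confidence interval on $W'$ exceeds 1, and avoided when the upper bound falls
below 1.

Two choices here were genuinely open:

* **Variance of $W'$.** The source framework reports selectivity ratios with
  error bars but no variance formula. We use the standard design-1 estimator
  with availability treated as known, $\mathrm{var}(\hat w_i) =
  o_i(1-o_i)/(n\,p_i^2)$ on the raw ratio $w_i = o_i/p_i$, and propagate
  through the normalising sum treating that sum as fixed. Intervals are at
  level $\alpha/m$ (one interval per habitat, family size $m$, default
  $\alpha = 0.05$).
* **Counting unit.** Nests can be counted individually or by nest group;
  `seasonal_selection(unit =)` exposes both, defaulting to individual nests.
  Nests are stratified into seasons by the month they were recorded fresh.

The month-to-season calendar is configurable because transition months
straddle seasons in this climate; the default is LDS = Nov–Feb,
LRS = Mar–Jun, SDS = Jul–Aug, SRS = Sep–Oct (`season_calendar()`).

## The fruit preference scoring stack

Four quantities are computed per plant taxon, in sequence.

**Stem density** (stems/m²), from the plot inventories:
$D_i = \sum_k n_{ik} / (K S)$ with $K$ the total number of plots (including
plots where the taxon is absent) and $S$ the plot area (default 625 m²).

**Fruit Availability Potential**, monthly:
$\mathrm{FAP}_{ij} = \left(\sum_n SS_{nij} B_{nij} / N_i\right) D_i$, where
$SS_{nij}$ is the summed 0–2 fruiting score of monitored individual $n$ in
month $j$, $B_{nij} = \pi(\mathrm{dbh}/200)^2$ its basal area in m² (DBH in
cm), and $N_i$ the number of monitored individuals. Two open points were
resolved as follows: $SS$ pools all four recorded scores (unripe/ripe, on
tree/on ground; range 0–8), with a `ripe_only` switch restricting it to the
two ripe scores; and the operator precedence is read as the mean
score-weighted basal area per monitored individual multiplied by stand
density, matching the availability-index lineage (density × phenology ×
size) the formula descends from. Individuals not observed in a month
contribute a score of zero but still count in $N_i$.

**Fruit quantity** per fecal sample: zero fruits if no seeds; one fruit if
the seed count is below the taxon's mean seeds per fruit; otherwise seeds
divided by mean seeds, rounded *up*. Mass is fruits × mean fruit weight. For
taxa with uncountable seeds (figs) a calibrated seeds-per-fruit value
substitutes for the empirical mean.

**Mean Consumption Score**, monthly per ape:
$\mathrm{MCS}_{ij} = \frac{QF_{ij}}{\sum_i QF_{ij}} \times
\frac{Pf_{ij}}{NPf_j}$ — the taxon's share of the month's reconstructed fruit
mass times its frequency across that month's fecal samples. It lies in
$[0,1]$, and months with no reconstructed mass give 0 for all taxa.

**Global Importance Score**:
$\mathrm{GIS}_i = \frac{\sum_j \mathrm{MCS}_{ij}/\mathrm{FAP}_{ij}}{J}
\times Pe_i$, summing over months in which the taxon bore fruit
($\mathrm{FAP} > 0$), with $J$ the number of study months (default 12, fixed
from configuration rather than per-taxon observation spans) and $Pe_i$ the
number of months consumed divided by the number of months fruiting. Months
with consumption but no measured availability are excluded from the sum
while still counting in the $Pe$ numerator, so $Pe$ can exceed 1; such taxa
are flagged (`pe_gt_1`) rather than clamped, applying the definition
literally. Taxa never found in phenology (or never fruiting) cannot be
scored and are reported as unclassified (UC) below all ranked taxa; taxa
never consumed get GIS 0. Ranking is by descending GIS with alphabetical
tie-breaks; displayed values below 0.001 print as 0 but rank by the
underlying value.

## Fallback and preferred fruits, and consumption traits

Seasons are split into the two with higher summed FAP (over all taxa and
months) and the two with lower FAP; ties break by the fixed season order with
a warning. A taxon is a fallback candidate for an ape when it (a) fruited in
at least three seasons, (b) had higher mean seasonal FAP in the high seasons,
and (c) had higher mean seasonal MCS in the low seasons. The "negative trend"
of consumption against availability is operationalised as this high/low
contrast rather than a correlation: with only four seasonal values a
correlation coefficient is unstable, and the contrast is what the defining
description of fallback foods expresses. Taxa whose study-total MCS falls
below a floor (default 0.001, configurable — no published value exists) are
excluded as too rarely eaten to classify.

Per ape, the list-size target is the number of classified taxa divided by 3,
rounded half away from zero. Fallback species are selected before preferred
ones: candidates fill the fallback list (truncated by descending low-season
MCS if over target), and the preferred list then takes the top-GIS taxa not
already fallback. A taxon qualifying as both is therefore fallback. The
per-ape statuses collapse to six plant consumption traits (Preferred/Fallback
× gorilla/chimpanzee/apes); the cross-ape conflict case (preferred for one
ape, fallback for the other) is not covered by the six traits and resolves to
the fallback side, extending the fallback-first rule.

## Ordination and seasonal tests

Plot stem counts are summed into a habitat × trait (or habitat × taxon)
contingency table; taxa with no trait are excluded, and plots left with no
stems of any included taxon are dropped with their count logged. Classical
correspondence analysis is applied: the standardized Pearson residual matrix
is decomposed by SVD, each axis carries inertia equal to its squared singular
value, and total inertia equals $\chi^2/n$. Row and column scores are
reported in principal coordinates for both sets (the symmetric biplot
convention), and the observed-minus-expected deviation table — whose rows and
columns sum to zero by construction — is returned as the measure of which
habitat/trait combinations drive the association.

Seasonal variation in the monthly FAP and MCS profiles (months as
replicates) is tested by one-factor PERMANOVA on Bray–Curtis dissimilarities:
pseudo-$F$ from the distance-based sum-of-squares partition, $p = (1 +
\#\{F^* \ge F\})/(1 + n_{perm})$ under unrestricted label permutation, with a
full-enumeration mode for small two-group designs. The companion dispersion
homogeneity test embeds the distance matrix by principal coordinates
(negative-eigenvalue axes enter squared distances with a negative sign, the
usual semi-metric correction), measures each month's distance to its season
centroid, and permutes labels recomputing the one-way $F$ on those distances.
Degenerate inputs are defined rather than fatal: all-zero profile pairs get
Bray–Curtis distance 0 with a warning, a perfectly independent contingency
table yields zero axes, and configurations in which all centroid distances
are numerically equal give $F = 0$.

## The synthetic-data generator

`generator_config()` fixes the study conditions; `generate_dataset()` draws
one realisation. The defaults emulate a realistic field design of this kind:
20 transects × 120 stations for availability (2,400 multinomial draws over
habitat weights MF 0.45, YSF 0.20, SW 0.15, RF 0.12, LG 0.08); 184 botanical
plots of 625 m² allocated to the four inventoried habitats (light gaps are a
microhabitat and never hold plots), with Poisson stem counts concentrated in
one primary habitat per taxon; 20 taxa with ~10 monitored phenology
individuals each (lognormal DBH around 30 cm) scored monthly, community
fruiting high in the rainy seasons and low in the dry ones; 30 fecal samples
per ape per month for 12 months; and 200 nests per ape per season.

Three couplings give the generator its known ground truth:

* **Consumption follows preference × availability, in mass.** Fruit counts
  per sample are Poisson with intensity proportional to the ape's preference
  weight times the month's realized population FAP, divided by the taxon's
  mean fruit weight (so preference governs mass intake regardless of fruit
  size, and the QF mass share recovers preference). Since GIS divides
  consumption by FAP, GIS is proportional to preference under this coupling
  — the property the rank-recovery tests exploit. Preference weights default
  to a geometric ladder from 0.2 to 5, in opposite taxon order for the two
  apes.
* **Designed fallback taxa.** Three taxa fruit year-round but have
  consumption intensity boosted fivefold in the low-availability seasons —
  exactly the signature (availability trend up in high seasons, consumption
  trend up in low seasons) the fallback classifier is built to detect.
* **Habitat selection on the $W'$ scale.** Nest habitat probabilities are
  availability × weight with weights averaging 1, so the configured weight
  *is* the expected $W'$. Strong designed effects (gorilla SW 2.4, MF and RF
  0.4; chimpanzee MF 2.4, YSF 0.4) sit on habitats common enough for the
  design to have power: a design-1 power calculation shows the Bonferroni
  interval for a weight-0.4 habitat of availability ≥ 0.12 clears 1 in ≈99%
  of replicates at 200 nests per season, whereas the rare light-gap habitat
  (availability 0.08) would be hopelessly underpowered, so its weights stay
  near 1.

What the generator does **not** emulate: spatial autocorrelation between
plots or transects, observer error in nest ageing and habitat assignment,
inter-annual phenology variation (all tables come from the same generating
year), group structure of nests (nests are independent draws; the counting
unit remains configurable downstream), and non-fruit dietary items. Passing
recovery tests therefore demonstrate that the pipeline's inference is
faithful when the field design's assumptions hold, not that those
assumptions hold in any particular forest.

## Numerical choices and problem sizes

* Chi-squared and CA computations restrict to categories with positive
  expectation; a CA axis is kept when its singular value exceeds $10^{-10}$
  times the largest.
* Permutation p-values use the add-one convention and a $10^{-12}$ slack on
  the $F^* \ge F$ comparison to absorb floating-point ties; exact enumeration
  (two groups) includes the observed assignment.
* Rounding: the list-size target rounds half away from zero; fruit counts
  round up.
* The test suite validates the permutation machinery at small sizes chosen
  for exactness rather than realism: exhaustive enumeration on all two-group
  splits of up to 8 points, a 2,000-replicate × 999-permutation type-I-error
  calibration on 12 months × 4 seasons, and 100-replicate recovery studies
  at the full default generator sizes. These sizes keep the suite's runtime
  in minutes while leaving the statistical checks at full strength.

## Known limitations

* The Pe > 1 convention (no clamping) follows the literal definition; users
  who prefer capping consumption months to fruiting months can filter on the
  `pe_gt_1` flag.
* Fallback candidacy requires availability data: a taxon consumed but never
  monitored in phenology is UC and cannot be a candidate, even when its
  consumption pattern alone looks fallback-like; such UC-vs-status conflicts
  between the two apes are reported in the trait assignment.
* With four seasonal values per taxon the high/low contrast is a coarse
  trend measure; it is deterministic and reproducible but insensitive to
  within-season timing.
* CA coordinates use symmetric (principal/principal) scaling; software using
  row-principal scaling will differ by axis-wise constants though inertias
  agree.
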