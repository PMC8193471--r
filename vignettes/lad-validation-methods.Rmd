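---
title: "The LaD monitoring algorithm and its expert-validation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The LaD monitoring algorithm and its expert-validation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladmonitor)
```

## The monitoring model

The package encodes an abridged labor-and-delivery monitoring logic for
settings where tracking all twelve WHO partograph parameters is not
feasible. Six parameters are monitored: fetal heart rate, amniotic
fluid, cervical dilatation, uterine contractions, maternal blood
pressure, and — replacing the maternal pulse — second-stage tracking of
the fetal station as a surrogate for fetal descent. Each parameter has
a classification into named states via configured normal ranges, a
monitoring interval on the 30-minute-to-4-hour grid, and an applicable
labor stage. The defaults follow conventional intrapartum norms (fetal
heart rate normal at 110–160 bpm; blood pressure normal below 140/90
mm Hg; active-phase progress assessed against the 1 cm/h alert-line
convention at 4-hourly examinations; contraction adequacy at 3–5 per
10 minutes) but every range, interval and label is overridable in the
YAML configuration — configurability, not any particular guideline, is
the contract. The `active_phase_start_cm` field (default 5 cm) is
carried as configuration metadata only; it does not affect enumeration.

The decision logic is recursive in structure: each abnormal parameter
is managed *independently* by a configured rule, and the final
management decision combines the per-abnormality outcomes. Rather than
simulating management over time, the success or failure of managing a
subabnormality is encoded statically in the scenario coordinate itself
(for example `slow_responding` versus `slow_persistent` cervical
progress), which makes the whole logic a finite, exhaustively testable
function: every abnormal coordinate contributes its rule's actions and
a resolved/unresolved outcome, and any unresolved critical outcome
forces the escalation/delivery track of the final decision, otherwise
the routine-monitoring track is taken. Escalation is therefore
monotone: adding an unresolved abnormality to a scenario can never
remove the escalation actions, a property the test suite checks over
perturbed scenario pairs.

## The scenario space

Only the total count of scenarios (1152) and the three amniotic-fluid
strata are fixed by the validated design; the exact factorization
behind that count was a genuinely open choice. The shipped default is
one consistent reconstruction:

amniotic status (3) × fetal heart rate (4) × cervical progress (4) ×
uterine contractions (4) × blood pressure (2) × fetal descent (3) =
1152.

The loader validates the product against the `expect_total_scenarios`
flag, so alternative reconstructions remain loadable by changing or
dropping that flag. Enumeration is the Cartesian product in
lexicographic order of factor definition (first factor most
significant), with `scenario_id` equal to the zero-based position; the
suite checks that every random coordinate draw appears exactly once.

The 22 candidate actions of the validation questionnaire were likewise
never published verbatim; the default catalog uses clinically phrased
labels with stable ids. All statistics depend only on the ids, so the
wording is cosmetic and configurable. At most 16 of the 22 actions may
be selected per case; the worst-case union of rule actions plus the
final-decision actions in the default configuration reaches exactly
that cap and the coverage test asserts it for all 1152 scenarios.

## Stratified case sampling

Validation cases are drawn by stratifying the scenario space on
amniotic fluid status (membranes intact / fluid clear / fluid opaque or
foul smelling; 384 scenarios each by construction) and sampling
`per_stratum` scenarios uniformly without replacement from each stratum
— two per stratum in the original design, giving six cases. The
original study used an external online random number generator; the
package instead uses a seedable partial Fisher–Yates shuffle with the
seed recorded in the sample object, trading fidelity to the original
tool for exact reproducibility. Uniformity is verified against the
brute-force enumeration of all pairs from a small stratum. Dropout
(the original sixth case, answered by only two of five experts) is not
modelled by the sampler; completeness filtering lives in the analysis
step, which drops any case not answered by every human rater before
computing statistics.

## The agreement framework

Let R and T be a reference and a test rater with selected action sets
for one case. The framework computes:

- unadjusted sensitivity |T ∩ R| / |R|, undefined when the reference
  selected nothing;
- weighted sensitivity, with numerator and denominator summing
  per-action consensus weights (the fraction of *human* experts
  selecting the action — never the algorithm's own selections, so
  algorithm-selected actions can carry weight 0);
- false-positive rate |T \ R| / (n_actions − |R|). The denominator —
  the actions the reference deems unnecessary — is the standard 2×2
  contingency choice with the reference as truth; it was an open
  design point and is stated here rather than hidden;
- the selection correlation r = √(sens(R→T) · sens(T→R)), symmetric by
  construction, preferred over kappa/pi because candidate actions are
  not selected independently of one another;
- the reliability coefficient α = kR/(1 + (k−1)R). Per-rater α uses
  that rater's mean pairwise correlation across partners and cases
  (one 4-partner × 5-case block per reference expert for the
  five-expert design); the overall coefficient is the mean of the
  per-rater values.

Group scores average the directed statistic over all *ordered* pairs
(sensitivity is directional; 20 pairs for five experts) or over each
expert as reference against the algorithm. Undefined pair scores are
excluded from averages with an explicit exclusion count — imputing 0
would conflate disagreement with missingness. Per-case group scores
are summarized across cases by the mean, the sample standard deviation
(n − 1 denominator) and the t-based 95% confidence interval
mean ± t(0.975, n−1)·sd/√n; these conventions were recovered exactly
from the published summary triples and are pinned by the acceptance
tests at the printed precision. Evaluators are ranked by the lower
border of the sensitivity CI (descending), then the upper border of
the FPR CI (ascending); evaluators whose intervals overlap on both
criteria are reported as statistically indistinguishable — on the
published group summaries this reproduces the finding of no
statistical difference between the algorithm and the human experts.

Two published quantities are deliberately **not** reproduced. The
difference-of-means confidence intervals printed alongside the score
rows do not match any standard convention (paired t, pooled t, or z)
applied to the printed per-case values; the package therefore provides
Welch's unpaired t (`compare_means`) as a transparent default and makes
no claim of matching those intervals. Similarly, the printed SD of
0.06 for the overall mean correlation of 0.67 is not recoverable from
the correlation table under per-case grouping (0.077) or per-pair
grouping (0.114); the mean itself reproduces and the SD is not
asserted.

## The synthetic panel generator

`lad_panel()` defines the generative model used to test the framework
end to end: for each (case, action) a latent selection probability p is
drawn from the symmetric two-parameter Beta(1/c, 1/c) distribution,
where c is the consensus concentration; each of k raters then selects
each action independently with probability p, and blocks exceeding the
selection cap drop their lowest-p selections (deterministic given the
draw, preserving high-consensus actions). Large c pushes p toward
{0, 1} — near-identical raters; c → 0 pushes p toward 1/2 —
independent coin-flip raters; c = 1 is uniform p. The defaults (k = 5,
5 cases, 22 actions, cap 16) mirror the validation study design. The
generator emulates consensus structure only: it has no per-rater
bias, no case difficulty, and no clinical correlation between actions,
so passing recovery tests demonstrates the statistics' correctness, not
realism of expert behavior.

Agreement recovery (`recover_agreement`) checks that mean r_selection
and mean α increase strictly with c (three levels × 200 replicate
panels in the acceptance suite, a few seconds of runtime). A
calibration pre-run of the generator put c = 1.1 at mean
r_selection ≈ 0.67 for k = 5, the agreement level of the original
panel; at that level the simulated overall α lands within 0.03 of
0.91, a self-consistency check of the reliability formula, not a claim
about the real experts (whose raw selections were never published).

## Numerical and testing choices

Continuous classification uses left-closed bins via `findInterval`, so
a boundary value belongs to the upper state (160 bpm is normal, 161 is
not, matching an integer-bpm reading convention). Percentages are kept
on the 0–100 scale throughout the analysis layer; rounding to the
published precision (one decimal for percentages, three for
correlations) happens only in the reporting layer. The shipped
reference tables are guarded by a checksum over every numeric value.
Test problem sizes — 1000 tiny matrices for the symmetry property,
10 000 seeded draws for sampling uniformity, 300 replicate panels for
the Beta-Bernoulli mean, 200 replicates per consensus level for
recovery — were chosen so the whole suite runs in about two minutes on
one core while keeping Monte-Carlo standard errors well inside the
asserted tolerances.

## Limitations

The factorization and action catalog are reconstructions constrained
only by the published counts; per-scenario recommendations are
therefore defaults, not the original study's unpublished answer key.
The engine is a static scenario classifier — it does not simulate
labor progression in time, device integration, or alarm behavior. The
agreement framework assumes complete-case analysis after filtering and
does not model rater dropout or fast/slow-actor behavior.
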