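---
title: "Single-molecule HLA-DR/DQ eplet mismatch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule HLA-DR/DQ eplet mismatch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epletmm)
```

## The problem

After kidney transplantation, de novo donor-specific antibody (dnDSA)
against mismatched HLA-DR or HLA-DQ is an established biomarker of primary
alloimmunity, preceding rejection and graft loss. Classical antigen-level
matching counts mismatched serologic antigens (0–2 per locus), but a
single antigen mismatch can hide anywhere from zero to dozens of
mismatched *eplets* — small patches of polymorphic, surface-exposed amino
acids that form the actual antibody footprints. `epletmm` implements the
molecule-level analysis of this mismatch: each donor HLA molecule is
scored individually against the recipient's whole same-class repertoire,
and each recipient is summarized by the *maximum single-molecule eplet
mismatch* per class, the quantity that tracks dnDSA risk.

## Scoring model

**Scorable units.** For HLA-DR, every expressed donor β chain is a
molecule: two DRβ1 (one per DRB1 allele, homozygotes counted twice) and
zero to two DRβ3/4/5 (null alleles encode no protein, contribute no
molecule, and never count toward totals). For HLA-DQ, the α and β chains
inherited on one haplotype form one DQα₁β₁ heterodimer, so every subject
contributes exactly two DQ molecules; a DQ molecule's eplet set is the
union of its DQA1 and DQB1 allele sets.

**Mismatch.** For donor molecule $m$ with eplet set $E_m$ and recipient
repertoire $R$ (all recipient molecules of the same locus class),

$$\mathrm{mm}(m) = \left| E_m \setminus \bigcup_{r \in R} E_r \right|,$$

i.e. the count of donor eplets absent from every recipient molecule of
that class. The recipient-level scores are
$\mathrm{DR}_{\max} = \max_m \mathrm{mm}(m)$ over donor DRβ1/3/4/5
molecules and $\mathrm{DQ}_{\max}$ over donor DQ heterodimers. The
comparison is within locus class only; cross-class eplet sharing is
ignored by design. DQ interlocus eplets that exist only on a specific
α–β pairing are representable only as eplets attached to a single α or β
allele; truly pair-dependent eplets are out of scope.

**Directionality.** Mismatch is donor-minus-recipient: swapping roles
generally changes the score.

## Typing resolution and imputation

Eplet assignment needs two-field (protein-level) alleles. Historical
typings are often one-field, and DQA1 may be missing entirely. Low
resolution calls are completed against a population haplotype-frequency
table (DRB1~DRB3/4/5~DQA1~DQB1): among all haplotype pairs compatible
with the observed calls (per-locus matching, since observed typing is
unphased), the pair maximizing the product of the two haplotype
frequencies is chosen — a most-likely single assignment, not probability
weighting, which is flagged as a design choice. Ties are broken by
lexicographic order of the concatenated haplotype strings so imputation
is bit-reproducible. Subjects whose stated population is absent from the
table fall back to a pooled (frequency-summed) table. The imputed typing
is returned haplotype-ordered, which fixes the DQα₁β₁ pairing phase.

## Risk categories

Two built-in threshold schemes stratify $(\mathrm{DR}_{\max},
\mathrm{DQ}_{\max})$:

* **Published ("wiebe")** — LOW: DR < 7 and DQ < 9; HIGH: DQ ≥ 15;
  otherwise INTERMEDIATE.
* **Cohort-specific ("nucot")** — LOW unchanged (DR < 7 and DQ < 9);
  HIGH: DR ≥ 12 **and** DQ ≥ 15 (conjunction); otherwise INTERMEDIATE.

The conjunction reading of the cohort-specific HIGH rule is a documented
interpretation: the source text states the two thresholds jointly, and
the conjunction is corroborated by the high-category share shrinking
(35% under the published rule vs 15% under the cohort-specific rule).
Whether an extreme DQ alone should reach HIGH under a disjunctive
reading cannot be decided from the text; the conjunction is implemented
and schemes are plain data, so a disjunctive variant can be expressed as
a user-defined scheme without code changes. Boundary semantics are
exactly as printed: strict `<` for LOW, `>=` for HIGH.

## Two-stage threshold derivation

Cohort-specific thresholds are derived in two stages:

1. The published LOW definition is retained (it already isolates a
   near-zero event-rate stratum).
2. LOW recipients are removed, and a per-class ROC analysis is re-run on
   the remaining *molecule-level* data: one observation per donor
   molecule, score = its mismatch count, label = dnDSA developed against
   that molecule. Recipient-level clustering is ignored, as in the
   source analysis. The Youden-optimal cutpoints become the HIGH
   thresholds of a conjunction rule.

AUC is the Mann–Whitney probability with ties counted ½. The cutpoint
criterion is not stated in the source; Youden's J (sensitivity +
specificity − 1) is used, with ties broken toward the *higher* threshold
because clinical categorization favours fewer false high-risk calls.
Both choices are configurable facts of this implementation, not claims
about the original analysis. The DR and DQ ROC analyses are run
independently per class; whether the original derivation considered them
jointly is not derivable from the text.

## dnDSA events and survival analysis

A detection qualifies as a dnDSA event when its MFI ≥ 500 (single-antigen
bead scale), it falls after the 14-day memory window (earlier DSA
indicates pre-transplant sensitization and excludes the recipient), and
its specificity attributes to a donor molecule of that locus class
(two-field exact match, first-field prefix otherwise; serologic labels
like "DR4" resolve by the prefix rule or are rejected per configuration).
Third-party antibodies censor rather than count. Event time is the first
qualifying detection day / 365.25; otherwise censoring at last follow-up.
Death and graft loss are treated as censoring (the source is silent on
competing risks; this is a stated limitation, not a modelling claim).

Kaplan–Meier curves, two-sided log-rank tests (all pairwise category
contrasts, unadjusted — no multiplicity correction, matching the source's
reporting), and Cox proportional-hazards models with Efron tie handling
come from the `survival` package behind contract-checked wrappers.
Categorical covariates are fit against declared reference levels and all
pairwise category contrasts (intermediate vs low, high vs intermediate,
high vs low) are derived from the coefficient covariance.

## The synthetic world

Because the motivating cohort is private, every stage is exercised on
synthetic data whose statistical structure mimics it. The generator is
fully deterministic given a seed.

**Registry.** Eplet sets are built from family blocks: the DR variable
pool of 21 eplets is partitioned into 3 allele families, the DQ α (12)
and β (20) pools into 2 families each; an allele carries a shared core,
its whole family block, and a graded extension into the neighbouring
block. Each locus also has one core-only and one full-pool allele, so the
printed mismatch ranges (DR 0–21, DQ 0–32) are achievable, and shared
cores guarantee the ranges are never exceeded. This mirrors how real
cross-serogroup mismatches produce broad, many-zeros score distributions.

**Haplotypes and populations.** 40 haplotypes are drawn
family-consistently (DRB1 and DRB3/4/5 from the same family; DQA1 follows
DQB1's family with probability 0.65, the remainder acting as
recombinant-like haplotypes that generate intermediate-size partial DQ
mismatches). About 12% of haplotypes carry a null DRB3/4/5 slot.
Population-specific frequencies are Dirichlet(2) draws with one boosted
anchor haplotype per population (Chinese/Malay/Indian), so the most
frequent haplotype differs across populations.

**Cohort.** Defaults mirror the target cohort: ethnicity mix
65/17/14/4 (Chinese/Malay/Indian/other, "other" drawing from the pooled
table), 44% deceased donors, cyclosporine 71%/tacrolimus 29%,
mycophenolate 88%/azathioprine 11%/none 1%, basiliximab 81%. Follow-up is
lognormal matched to median 5.4 years (IQR 3.3–8.0), floored at 0.5
years. Per-locus latent dnDSA times are exponential with rate
$\lambda_0 \cdot e^{\beta \cdot \text{max mismatch}} \cdot 1.66^{[\text{cyclosporine}]}$,
with per-eplet hazard ratios $e^{\beta_{DR}} = 1.3$ and
$e^{\beta_{DQ}} = 1.1$ (the reported univariate values) and the adjusted
cyclosporine-vs-tacrolimus multiplier 1.66 (the adjusted rather than
unadjusted value, because the adjusted model is what the pipeline
refits). Baseline hazards are not printed anywhere; they were chosen once
as $\lambda_{0,DR} = 0.0018$/yr and $\lambda_{0,DQ} = 0.0045$/yr,
calibrated so the realized per-locus event fractions at the realized
mismatch distribution match the printed incidence (18/234 DR, 22/234 DQ
over a median 5.4 years), and not revisited. Latent events surface at the
first annual screen (annual cadence is a modelling choice; the true
cadence beyond "at least yearly" is unknown and the interval is a
parameter), each screen detecting a prevalent dnDSA with probability 0.9
at a qualifying MFI drawn from a lognormal shifted above 500; misses
produce sub-500 screening rows, so the MFI ≥ 500 filter is non-trivial.
An `exact_times` switch bypasses screening discretization for clean
parameter-recovery experiments. 10% of subjects are emitted with
low-resolution typing to exercise the imputation path end-to-end.

**What the generator does and does not reproduce.** Realized category
proportions under the published scheme are ≈ 43/34/23 (LOW/INT/HIGH)
against the printed 30/35/35, and the zero-mismatch fraction is ≈ 0.22
vs the printed 0.10: a 40-haplotype, 2–3-family world cannot match every
marginal of real HLA diversity at once, and these two were left free once
the ranges, event rates, and bimodal shape were right. No real
population-genetic linkage structure, Class I or DP loci, rejection
episodes, graft loss, or competing risks are simulated. A green test on
this world therefore establishes algorithmic correctness and statistical
calibration of the pipeline — not clinical performance on any real
cohort.

**Molecule-level label simulator.** For cutpoint-recovery experiments, a
separate generator draws pair-correlated integer scores (two DR and two
DQ molecules per pair) and labels them through a step model
(P = 0.001 below the change-point, 0.25 at/above; change-points DR = 12,
DQ = 15) or a logistic link. The pair-level correlation gives a realistic
LOW stratum (≈ 20% of pairs) for the two-stage exclusion step.

## Numerical and engineering choices

* Exact integer set operations; no floating-point in scoring.
* The haplotype-pair mismatch cache used by large simulations is an
  incidence-matrix restatement of the engine, asserted equal to
  `recipient_mismatch_summary()` in the tests and spot-checked at
  acceptance time; it is an optimization, never a second definition.
* Cox models use Efron's tie approximation; days convert to years by
  365.25; separation is flagged with an unbounded-estimate warning.
* Detections with missing MFI are screening-only by default (configurable
  to a hard error).
* The pipeline writes no timestamps; reports under a fixed seed/config
  are byte-identical, and the report embeds the package version, seed,
  and a config fingerprint.

## Known limitations

* Imputation returns the single most likely haplotype pair; posterior
  mass over near-tied pairs is discarded.
* Serologic broad/split antigen dictionaries beyond the first-field
  prefix rule are not implemented.
* dnDSA-free survival ignores competing mortality; with heavy competing
  risk the Kaplan–Meier complement overstates cumulative incidence.
* The two-stage derivation inherits the instability of ROC cutpoints in
  small event counts; the error path (no informative data after LOW
  exclusion) is deliberate and loud.
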