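---
title: "Defining chronic dialysis from outpatient claims: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining chronic dialysis from outpatient claims: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialclaims)
```

## The problem

Patients with end-stage renal disease (ESRD) on chronic hemodialysis or
peritoneal dialysis are a small (about 0.2% of the adult population),
high-morbidity group that health-services researchers routinely need to
identify. Dedicated ESRD registries are the reference standard for who is on
chronic dialysis, but they are not universally accessible. Physician billing
claims are: every outpatient dialysis encounter generates a claim carrying a
procedure code. A *case definition* (phenotyping algorithm) is a rule over a
patient's dated claims that labels them as receiving chronic dialysis; its
validity is quantified by comparing it against a registry on the same
population.

`dialclaims` implements the four temporal case definitions used in the
Alberta validation of outpatient CCP dialysis codes, the index-date rule for
cohort entry, the agreement statistics that validation reported, and a
synthetic claims generator so the whole pipeline is exercisable without any
real (and confidential) administrative data.

## The case definitions

All definitions operate on a patient's *claim days*: the distinct calendar
dates inside the observation window on which the patient has at least one
outpatient claim with a dialysis procedure code (default set:
`ccp_dialysis_codes()`, the six CCP codes 13.99A/B/C/D/O/OA). Collapsing to
days is a deliberate choice — two claims billed on the same day (distinct
codes, or an exact resubmission) carry no evidence of chronicity, and exact
duplicate rows are already dropped at read time.

For a sorted claim-day vector $d_1 < d_2 < \dots < d_n$:

* **d1** — at least 1 claim day ($n \ge 1$);
* **d2** — at least 2 claim days ($n \ge 2$);
* **d3** — two claim days at least 90 days apart ($d_n - d_1 \ge 90$; the
  extremes realise the maximum over all pairs, so no pair scan is needed);
* **d4** — a *continuous* run: some consecutive sub-sequence
  $d_i, \dots, d_j$ with every successive gap $\le 21$ days and span
  $d_j - d_i \ge 90$ days.

Boundary conventions follow the literal reading of the definitions: "at
least 90 days apart" is inclusive (span of exactly 90 qualifies) and "no gap
greater than 21 days" is strict (a gap of exactly 21 does not break a run).
All differences are whole calendar-day counts; no month arithmetic.

`classify_d4()` does not enumerate sub-runs. It splits the series into
maximal runs at gaps exceeding 21 days and checks each maximal run's span:
any qualifying sub-run lies inside one maximal run, and within a maximal run
the full span is the largest. The test suite verifies this equivalence
against a brute-force enumerator on 10,000 random series. Two consequences
are property-tested: the definitions nest (d4 ⟹ d3 ⟹ d2 ⟹ d1) and any
d4-positive series has at least 6 distinct claim days (90 days bridged by
gaps of at most 21 needs at least ⌈90/21⌉ = 5 gaps).

The qualifying run may occur anywhere in the window; we do not anchor it to
the first claim. The per-week management codes (13.99O, 13.99OA) are treated
as point events on their service date, not as 7-day coverage intervals —
coverage semantics would change the 21-day gap rule in a way the original
definitions never specify.

**Index date.** Cohort entry is the date of the *second* claim day. Only
`d1` admits patients with a single claim day; for those the first (only)
claim day is used, as no second exists. `assign_index_date()` refuses
patients who are not positive under the requested definition.

## Agreement statistics

Validation against the registry reference standard uses the 2×2 table with
cells $a$ (both positive), $b$ (claims only), $c$ (registry only), $d$
(neither), $N = a+b+c+d$:

* sensitivity $= a/(a+c)$,
* positive predictive value $= a/(a+b)$,
* positive agreement $= 2a/(2a+b+c)$ (Cicchetti–Feinstein proportion of
  specific positive agreement),
* Cohen's kappa $= (p_o - p_e)/(1 - p_e)$ with $p_o = (a+d)/N$ and
  $p_e = [(a+b)(a+c) + (c+d)(b+d)]/N^2$,
* claims prevalence $= 100\,(a+b)/N$ percent.

When the outcome is rare ($d \gg a,b,c$), $p_e \to$ the proportion negative
under both and kappa converges to the positive agreement; on the published
counts the two differ by under $10^{-3}$, which is why the two columns print
identically. This limit is asserted in the tests both on the published rows
and structurally (gap shrinking monotonically as $d$ grows).

Specificity, NPV and negative agreement are computable
(`include_negative = TRUE`) but suppressed by default: with over a million
true negatives they sit at 1.000 regardless of definition and carry no
information about the choice between definitions.

Numerical choices: statistics are kept at full precision internally;
rounding (half away from zero; 3 decimals for proportions and kappa, 2 for
prevalence percent) happens only at report serialization. Counts are stored
as doubles because the kappa chance term multiplies margins of order $N$ and
overflows 32-bit integers at population scale. Landis–Koch bands are
half-open with the upper bound included (0.80 is still "substantial",
anything above is "near perfect"); because a kappa that is mathematically
exactly on a boundary can land a floating-point ulp above it, values are
snapped to 9 decimals before banding. Degenerate tables (no registry
positives, no claims positives, chance agreement 1) raise explicit
undefined-value errors rather than returning `NaN`.

## The synthetic generator

`simulate_claims()` exists so the full pipeline — file layouts, readers,
definitions, validation — runs end to end with known ground truth. Its
defaults are fixed study conditions, not tuning knobs:

| parameter | default | why |
|---|---|---|
| `n_population` | 1,000,000 | population-scale denominator, same order as a provincial adult laboratory cohort |
| `registry_prevalence` | 0.002 | chronic dialysis is roughly 0.2% of such a population |
| `prevalent_fraction` | 0.75 | most registry patients at any time are prevalent, not incident-this-year |
| `modality_mix` | 0.8 | about four in five dialysis patients are on hemodialysis |
| `hd_claim_period_days` / billing | 7, per-week code 13.99OA | matches the per-week management billing of the CCP code set; a per-session mode (13.99B) is available |
| `pd_claim_period_days` | 30 | monthly peritoneal dialysis management contact |
| `claim_capture_prob` | 0.9 | missed billings, billing errors, shadow billing by salaried physicians |
| `aki_rate` | 5e-4 | occasional temporary dialysis for acute kidney injury among non-registry patients |
| AKI duration | gamma, mean 21 sd 14, truncated to [1, 89] days | temporary dialysis resolves within three months; truncation below 90 days makes AKI episodes d3/d4-negative *by construction* (configurable upward to study boundary leakage) |
| `early_death_hazard` | 0.001/day | early mortality after dialysis initiation (~9% by day 90); death halts claim emission the same day |

A one-day AKI episode degenerates to a single stray claim — the shape of an
isolated billing error — so stray claims need no separate mechanism.
Everything is seeded: one integer seed reproduces the claims, registry and
truth files byte for byte.

What the generator emulates and what it does not: it produces the *error
taxonomy* that separates claims from registry (temporary dialysis inflating
the lenient definitions' false positives; incomplete capture inflating false
negatives, hardest on the gap-sensitive continuous definition; early death
interacting with 90-day rules) with regular billing periods. Real billing is
irregular — holidays, hospitalizations that interrupt outpatient billing,
modality switches — and real capture failure is probably patient-clustered
rather than claim-independent. Passing tests on simulated data therefore
demonstrate that the algorithms and statistics behave correctly under the
assumed error structure; they do not calibrate, and cannot reproduce, the
absolute published statistics, which depend on unobservable real noise
rates. The direction-of-effect tests (more AKI lowers d1 PPV but spares d4;
lower capture hurts d4 sensitivity fastest) assert exactly the qualitative
findings the validation reported, on 20-replicate averages at a population
of 20,000 per replicate — sizes chosen to make the comparisons stable while
keeping the default test run fast.

## The pipeline and its population

`run_validation()` reads claims and registry files, classifies every
patient under the requested definitions, and emits one agreement-report row
per definition plus cohort summaries. One design point deserves emphasis:
the study population (the denominator $N$, hence $d$ and kappa) defaults to
the union of patient ids seen in the inputs. The original validation's
population was everyone with an outpatient serum creatinine that year —
a laboratory cohort that cannot be reconstructed from dialysis claims.
When $N$ matters, pass `population` (a vector of ids or a file) to pin it;
$a$, $b$, $c$ are unaffected by that choice, only $d$ moves. The published
2×2 counts ship with the package (`published_counts()`) so every reported
statistic is reproducible exactly without any real data.

Re-running the pipeline on identical inputs is byte-identical: nothing in
the classification or reporting path draws random numbers.

## Known limitations

* The claim-day counting rule (same-day claims collapse) and the
  any-qualifying-run reading of "continuous" are the package's choices where
  the original definitions are silent; a study that counted raw claims or
  anchored runs at the first claim could classify borderline patients
  differently.
* Per-week codes as point events understate coverage for weekly-billed
  patients with a single missed week near the 21-day boundary.
* The generator's regular-period billing is a simplification (noted above).
* No confidence intervals are computed for the agreement statistics, and no
  modality-specific (HD vs PD) definitions are provided — administrative
  data identify dialysis per se more reliably than modality.
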