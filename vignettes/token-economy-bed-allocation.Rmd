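---
title: "Token-economy bed allocation: model, mechanics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Token-economy bed allocation: model, mechanics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tokenward)
```

## The problem

Hospital bed allocation suffers from information asymmetry: a central
allocation manager sees the whole hospital's demand but not the true burden on
each ward's nursing staff, while each ward manager knows their own burden but
has no credible channel to express it. `tokenward` simulates a market-style
alternative: each ward posts a *price*, in a virtual token currency, for
admitting each kind of patient. A physician agent pays the posted price when it
admits a patient, so a ward that is overloaded can raise its prices — the price
list becomes a *signal* of the ward's hidden workload state, and no central
manager is needed.

The simulator is a game engine: the pricing side can be played by a human at a
terminal (`cli("play", ...)`), driven by recorded schedules, or run fully
autonomously with parameterized policies.

## The model

A hospital has $W$ wards (default 3, labelled A–C, 40 beds each), each
specializing in one illness. Patients come in $I \times S$ types — illness
$\times$ severity (default $3 \times 3 = 9$: gastric ulcer, pneumonia, heart
failure; mild, moderate, severe).

**Workload.** Each ward carries a scalar workload, the simulator's proxy for
nursing burden. Admitting a patient adds an increment $w(s, \text{match})$
from the weight table:

| severity | matched | mismatched |
|----------|---------|------------|
| mild     | 1.0     | 1.5        |
| moderate | 1.25    | 1.8        |
| severe   | 1.5     | 2.25       |

A mismatched admission (illness $\ne$ ward specialty) costs roughly 50% more.
The shipped mismatched-moderate default is 1.8 even though an exact +50% on
1.25 would be 1.875; both the table rows are configuration, so
`weights: {mismatched: {moderate: 1.875, ...}}` gives the exact-surcharge
variant. We deliberately ship 1.8 rather than silently "correcting" it, and
the weight-ratio unit test pins 1.8/1.25 = 1.44.

Discharge reverses the *stored* per-patient increment, not a recomputation, so
the running workload satisfies an exact identity with the sum over current
occupants (tested to $10^{-9}$).

**The daily loop.** Each simulated day:

1. every ward's pricing policy posts a complete price list (one non-negative
   token price per patient type), computed from that ward's restricted view;
2. `arrivals_per_day` patients (default 7) are drawn i.i.d. from the arrival
   distribution over types (default uniform over the 9);
3. the physician agent places each arrival in sequence, each seeing the
   vacancies left by its predecessors; every admission transfers the posted
   price to the ward's token balance (a rejection is logged when no ward has
   a bed);
4. each occupant admitted before today is independently discharged with
   probability $1/\text{mean LOS}$ (default $1/14$).

Sessions run `n_days` (default 10) from an empty hospital.

**The physician rule.** For a patient of type $t$, let $C$ be the wards with a
vacancy and $p_{\min} = \min_{c \in C} p_c(t)$. If the patient's specialty ward
$s \in C$, the agent draws a fresh acceptance multiplier
$m \sim U(\text{lo}, \text{hi})$ (default $U(1, 2)$) for this decision and
admits to $s$ iff $p_s(t) \le m\,p_{\min}$ — the premium the physician will
tolerate for a specialty placement. Otherwise (and when the premium is
refused) it admits to the cheapest vacant ward, ties broken uniformly at
random. Since $m \ge 1$, a specialty ward matching the minimum price is chosen
with certainty; a specialty ward at ratio $r = p_s/p_{\min}$ is chosen with
probability $\min(1, \max(0, (\text{hi} - r)/(\text{hi} - \text{lo})))$, the
closed form the Monte Carlo tests check against. We read "an additional price
is acceptable" as multiplicative because the multiplier's lower bound of 1.0
is stated to mean *no additional fee*, which only a multiplier on the best
competing price satisfies.

**Length of stay.** The only stated discharge parameter is a mean stay, so we
use the memoryless discrete-time process consistent with it: per-day Bernoulli
discharge at $p = 1/\text{mean}$, i.e. geometric LOS with support starting at
1 day (same-day admissions are ineligible for that day's draw, which both
prevents zero-length stays and keeps the mean at exactly $1/p$). Note that in
a finite session the mean over *completed* stays is right-censored and biased
low by a few tenths of a day; the LOS-recovery tests therefore either run the
discharge process to completion (`simulate_stays()`) or restrict to
admissions with at least 100 days of follow-up, where the censoring
probability is $e^{-100/14} \approx 8 \times 10^{-4}$.

**Information asymmetry as a type.** A pricing policy consumes a `ward_view`,
which contains the policy's own ward in full (occupancy, workload, balance,
price history) but only the *patient counts* of other wards. Other wards'
workloads, balances, and prices are not fields of the type, so a policy cannot
read them even by accident. Whether the original human players could see other
wards' prices is unstated; we default to the strict reading (counts only) and
expose `show_other_prices: true` for the relaxed variant.

**Tokens.** Settlement is pass-through: the hospital issues exactly the agreed
price per admission and the ward receives it, so total issuance equals the sum
of ward balances after every event (the closed-economy invariant) and a ward's
score is its gross token income. Physician-side budgets, token redemption, and
multi-session carryover are out of scope.

## Pricing policies

Policies stand in for the human nurse managers:

* `constant` — one base price everywhere, every day;
* `workload_linear` — $\text{price} = \text{base} + \text{slope} \times
  \text{own workload}$, clipped at 0; an optional `noise_sd` adds mean-zero
  Gaussian jitter per day and pattern. The jitter exists so that a
  *workload-blind* arm (slope 0) still has price variation: without it the
  zero-slope null has zero price variance and rank correlations are undefined
  rather than centered on zero;
* `random` — uniform prices on `[min, max]`, a price-noise control;
* `replay` — prices read from a recorded CSV schedule (`day, ward, illness,
  severity, price`), the format in which interactive sessions are recorded,
  so a human session replays bit-exactly;
* `interactive` — terminal prompts showing the same information the game's
  web interface showed.

## Signaling analysis

`extract_pairs()` reconstructs, purely from the event log, one
(workload-at-pricing, price) pair per day, ward, and pattern — 270 pairs for
a default session. "Workload at pricing time" is the instantaneous day-start
value, before that day's arrivals and discharges, matching the game flow in
which prices are set at the start of the day; no per-day averaging across
patterns is applied. `association()` reports both Pearson's $r$ and
Spearman's $\rho$ per group because the signaling claim is qualitative — the
relation need not be linear or even monotone every day — and flags degenerate
groups (constant prices, constant workload, or fewer than 3 pairs) instead of
fabricating coefficients. No significance testing is attached by default
(the correlations describe a single simulated session, not a sample);
`stats::cor.test` can be applied to the pair table when wanted.

The mechanism's testable core is *signal recovery*: sessions driven by
`workload_linear` policies with positive slope must yield positive $\rho$ in
every non-degenerate group, while zero-slope (noise-only) policies yield
$\rho$ centered on zero across replicates. The acceptance suite runs exactly
this experiment.

## Command-based baseline

`command_select()` models the centralized alternative: the allocation manager
forces the specialty ward when it has a bed and otherwise falls back to the
least-occupied (or a random) vacant ward, ignoring prices entirely.
`compare_mechanisms()` runs paired replicates — one seed drives both arms, and
the independent RNG substreams (arrivals, discharge, multiplier, tie-break,
policy) keep the patient stream identical across arms — reporting workload
balance, specialty-match fraction, and rejections per arm. The
negotiation-based method (human consensus) is documented but not simulated:
no behavioral model for it exists, and we decline to invent one.

## Reproducibility mechanics

Every session is driven by one seed expanded into named substreams, so
changing one process (say, `arrivals_per_day`) does not perturb the draws of
another (discharge). The event log — typed records of every price-setting,
arrival, admission, rejection, and discharge — is the single source of truth:
replaying it against an empty state reproduces the final state exactly, the
analysis is a pure function of it, and identical seed + config produce
byte-identical JSON-lines files. Output bundles include a manifest (config
hash, seed, version, file inventory) sufficient to reproduce the run.

Whether discharge precedes or follows the day's arrivals is not fixed by the
game description beyond "vacant beds appeared"; day-end discharge is the
shipped default and `discharge_timing: before_arrivals` exposes the
alternative rather than guessing intent.

## Problem sizes and numerical choices

The shipped scenario is deliberately small (3 wards × 40 beds, 7 arrivals/day,
10 days), so statistical checks run at larger derived scales chosen to make
their standard errors meaningful: 10,000 stays for LOS recovery (±2 SE),
10,000 selection replays for the premium probability (±3 SE, compared to the
closed form and an independent Monte Carlo oracle of the multiplier rule),
chi-square goodness-of-fit at $n = 10{,}000$ and $\alpha = 0.001$ for
tie-breaking and arrival uniformity, 100 replicates of 10-day sessions for
the zero-slope null, and ten 200-day runs (occupancy averaged over the last
100 days) for the long-run occupancy level
$\text{arrivals/day} \times \text{mean LOS} = 98$ beds of 120.

Other numeric choices: probability-mass validation tolerance $10^{-9}$;
workload identity tolerance $10^{-9}$; prices written to schedules at full
double precision (`%.17g`) so replay is bit-exact; negative computed prices
clip to zero with a warning rather than erroring, since a linear policy can
legitimately cross zero.

## What the generator does and does not emulate

The synthetic patient stream reproduces the study conditions: i.i.d. uniform
arrivals over 9 types, geometric stays, and stationary rates. Real admission
streams have day-of-week and seasonal structure, severity-dependent lengths of
stay, elective admissions competing with emergencies, inter-ward transfers,
and readmissions — none of which are modelled here, so passing tests certify
the mechanism's internal logic, not forecasting fidelity for any real ward.
Human pricing behavior is likewise represented only by the parametric
policies; the package makes no claims about what real nurse managers would do.

## Known limitations

* Wards are homogeneous except for specialty; no staffing levels, transfers,
  or elective streams.
* The physician agent is the fixed lowest-price-with-premium rule: no
  learning, budgets, or strategic behavior.
* Rejected patients vanish (logged, not queued); with the default scenario
  rejections are rare, but under stress the rejection count is the statistic
  to watch.
* Token balances are gross income; no redemption mechanism is modelled.
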