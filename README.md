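# tokenward

An agent-based simulator of **token-economy hospital bed allocation**.

Hospital bed assignment is usually run either by negotiation between managers
or by a central allocation manager with the authority to force wards to accept
patients. Both struggle with information asymmetry: the central manager sees
hospital-wide demand but not the true burden on each ward's nurses, and ward
managers have no credible channel to express that burden. `tokenward`
simulates a market-style alternative in which the bed assignment is a
transaction: each ward posts a *price* in a virtual token currency for each
kind of patient, and a physician agent pays the posted price on admission.
Overloaded wards raise prices; the price list becomes a signal of the hidden
workload state, and no allocation manager is needed.

The package is for health-systems and operations researchers who want a
reproducible testbed for mechanism questions (does pricing actually transmit
workload information? how does the market compare to command-based
allocation?) and for running the pricing game itself, interactively or from
recorded sessions.

## The model in brief

A hospital of $W$ specialty wards (default 3 × 40 beds) faces a stream of
patients typed by illness × severity (default 3 × 3). Each day:

1. every ward posts a price $p_w(t) \ge 0$ for each patient type $t$, seeing
   only its own state plus other wards' patient counts;
2. 7 patients arrive with i.i.d. uniform types;
3. for each arrival, among vacant wards $C$ with
   $p_{\min} = \min_{c\in C} p_c(t)$, the physician admits to the specialty
   ward $s$ iff $p_s(t) \le m\,p_{\min}$ with $m \sim U(1, 2)$ drawn fresh per
   decision, else to the cheapest vacant ward (ties uniform); the ward's
   token balance grows by the posted price;
4. each occupant is discharged with probability $1/14$ per day (geometric
   length of stay, mean 14 days).

Admission adds a workload increment: 1.0/1.25/1.5 points for mild/moderate/
severe patients matching the ward's specialty, 1.5/1.8/2.25 mismatched. The
analysis layer then asks whether posted prices track workload (Pearson *r*
and Spearman *ρ* per ward/pattern/pooled), and a command-based allocator
(specialty first, then least-occupied, price-blind) serves as the baseline.

## Worked example

Run the default 10-day scenario with wards that price linearly in their own
workload (base 2 tokens, 0.5 tokens per workload point):

```r
library(tokenward)
cfg <- scenario_config(
  policies = list(default = list(kind = "workload_linear", base = 2, slope = 0.5)),
  seed = 42
)
res <- run_session(cfg)
res
#> <session_result> token mechanism | 10 day(s) | 70 admission(s), 0 rejection(s)
#>   issuance 540.42 tokens | final occupancy: A=21, B=18, C=17

summ <- summarize_session(res)
summ$wards
#>   ward final_balance mean_workload max_workload mean_occupancy n_admissions specialty_match_fraction
#> 1    A           203          12.4         23.5            9.6           25                    0.920
#> 2    B           152          12.0         22.2            9.6           22                    0.955
#> 3    C           186          10.9         20.1            7.8           23                    0.696
```

All 70 arrivals found beds (120 beds, ~98 occupied in the long run). Ward A
earned 203 of the 540 issued tokens; 92% of its admissions matched its
specialty. The physician's premium rule explains the mismatches: when a
specialty ward's price exceeded the sampled multiple of the cheapest vacant
ward's price, the patient went to the cheaper ward.

Is the pricing signal recoverable from the public record? Pairs of (workload
at pricing time, posted price) are rebuilt from the event log alone:

```r
pairs <- extract_pairs(res$log)   # 270 pairs: 10 days x 3 wards x 9 patterns
association(pairs, "ward")
#>   group  n pearson_r spearman_rho degenerate
#> 1     A 90         1            1       none
#> 2     B 90         1            1       none
#> 3     C 90         1            1       none
```

Correlations of exactly 1 are expected here — the policy *is* linear in
workload; human or noisy policies give the partial associations the analysis
is designed to quantify. `compare_mechanisms(cfg, n_replicates = 10)` runs
the same seeds through the token and command mechanisms for the baseline
contrast, and `plot_price_workload(pairs)` draws the per-pattern scatter.

## Command line

A thin CLI wraps the same functions (see `inst/cli/tokenward`):

```sh
tokenward simulate --config inst/extdata/paper_default.yaml --seed 42 --out run1/
tokenward analyze  --log run1/events.jsonl --out run1/analysis/
tokenward play     --config inst/extdata/paper_default.yaml --out game1/   # interactive pricing
tokenward replay   --config inst/extdata/paper_default.yaml --schedule game1/schedule.csv --out game1-replay/
tokenward compare  --config inst/extdata/paper_default.yaml --replicates 10 --out cmp/
```

Every run directory contains the JSON-lines event log (byte-identical under
the same seed), CSV exports, a replayable price schedule, and a manifest
pinning the config hash and seed.

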