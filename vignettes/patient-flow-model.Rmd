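---
title: "Modelling inpatient electrophysiology patient flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inpatient electrophysiology patient flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epflowsim)
```

## The system being modelled

`epflowsim` simulates the inpatient journey through the cardiology
department of a large tertiary hospital in which electrophysiology (EP)
procedures — AF ablations, device implants and related interventions — are
performed in dedicated EP labs. Three patient classes compete for ward beds:

* **TEP** patients (target EP patients) are fully modelled: admission,
  a pre-operative stay, the EP-lab procedure, a post-operative stay,
  discharge. Only they use electrophysiologists and EP labs.
* **CLEP** patients (catheter-lab EP) and **NEP** patients (non-EP
  cardiology) occupy beds for their length of stay and are otherwise
  passive. They exist in the model because bed competition is the binding
  constraint in many departments.

The packaged default configuration (`default_config()`) describes a
department with 87 ward beds, two EP labs open Monday–Friday 08:00–22:00,
and two electrophysiologists on duty per workday, together with the
empirical arrival and duration summaries for eleven EP procedure classes.

## The simulated day

Each simulated day proceeds in a fixed order:

1. **Morning turnover** (default 07:00): every patient whose discharge day
   is today releases their bed, before any admission.
2. **Arrivals**: elective patients are scheduled daily, one hour before
   working hours, seven days a week. The per-class daily count is a
   negative binomial draw (below). Admissions follow the bed policy
   (below); a TEP admission samples its procedure class, length of stay,
   pre-operative stay, operative and clean-up times.
3. **The lab day** (workdays only): patients whose pre-operative phase is
   complete queue for the EP labs. A patient admitted on day $a$ with a
   sampled pre-operative stay of $k$ nights becomes eligible on day $a+k$
   ($k=0$ means same-day eligibility, which two procedure classes allow),
   deferred to the next workday if the labs are closed. Each eligible
   patient is assigned to one of the two on-duty physician slots by that
   weekday's historical allocation, re-drawn on roll-over days because the
   on-duty pair changes daily. Within a slot the queue is FIFO by (first
   scheduled day, admission day, id); labs are interchangeable
   (earliest-free). A procedure starts at the earliest instant at which its
   physician slot and any lab are both free, provided that instant is
   strictly before closing; a started procedure always runs to completion,
   after which the physician is released immediately and the lab after the
   clean-up time. Patients not started by closing roll to the next workday.

The run begins with a warm-up (default 10 days) carrying only CLEP/NEP
flow, so the ward reaches realistic occupancy before TEP arrivals start;
the observation window (default 61 days) counts TEP discharges.

## Input distributions

**Daily arrivals** are negative binomial, fitted by the method of moments
from the per-class mean $m$ and standard deviation $s$:
$r = m^2/(s^2-m)$, $p = m/s^2$, which reproduces $m$ and $s^2$ exactly.
When $s^2 \le m$ there is no over-dispersion to model and a Poisson with
mean $m$ is used instead.

**Durations** (stays in days, operative and clean-up times in minutes) are
truncated lognormal. Each duration is specified by the four numbers a
department can report — mean, SD, minimum, maximum — and fitted on the
natural scale: $\sigma^2 = \log(1 + s^2/m^2)$,
$\mu = \log m - \sigma^2/2$, then truncated to $[\min, \max]$. Sampling
inverts the truncated CDF (distributionally identical to rejection from
the untruncated lognormal, at fixed cost). Stays are rounded half up to
whole days and clamped to the integer range the bounds allow. A zero-SD
spec denotes a constant duration.

Because the reported moments describe *already-bounded* observations, the
realized (truncated, rounded) mean differs from the spec mean — for the
longest-staying ablation class by about +6%. The fit deliberately does not
re-solve for $\mu,\sigma$ under truncation: the simpler reading keeps the
mapping from published summary tables to model inputs transparent, and the
validation run shows the aggregate effect is absorbed by the system-level
calibration. The `lognormal_moments()` helper exposes the analytic
untruncated moments so users can quantify the gap per class.

**Pre-operative conditioning.** The post-operative stay is the difference
between the length of stay and the pre-operative stay, so the pre-op draw
is conditioned on the realized LOS by capping its truncation interval at
the LOS (equivalent to redrawing until compatible). This preserves the
pre-op distribution's shape below the cap and guarantees a non-negative
post-op remainder.

**Realized post-op.** Workday gaps and lab congestion can delay the
procedure past the sampled pre-op day. The model treats such delays as
eating into the post-operative remainder: discharge falls on
$\max(\text{admission} + \text{LOS}, \text{procedure day})$. The
alternative — appending the sampled post-op to whichever day the procedure
actually happens — systematically inflates every stay beyond the observed
LOS distribution (whose estimates already contain those delays in real
data) and noticeably under-predicts bed-limited throughput. Preserving the
sampled LOS is both statistically faithful to how the inputs were measured
and empirically the reading that reproduces the department's observed
discharge counts.

## Bed policy

An arrival finding the ward full joins a FIFO bed queue and is admitted
once a bed frees up (`bed_policy = "waitlist"`, the default); their stay
clock starts at admission. The alternative `"balk"` policy drops such
patients outright. Elective inpatient flow behaves like the former — a
fully booked department defers admissions rather than losing the patients —
and only the waitlist policy reproduces the observed totals: balking
selectively discards bed-only patients precisely when the ward is
saturated, which hands their beds to EP-lab patients and overstates
EP throughput by roughly a quarter in the bed-limited regime.

## Scenarios

Two capacity-limiting regimes are studied, each as a base case plus a grid
of process improvements (`scenario_grid()`, 26 cells):

* **Fully occupied wards** (`cls_wards_base()`): resources unchanged; TEP
  arrivals switch to a *saturating* regime that generates exactly enough
  TEP patients each morning to fill every bed left after the bed-only
  classes are admitted.
* **Fully occupied EP labs** (`cls_eplabs_base()`): beds raised to 110,
  labs cut to one, saturating TEP arrivals, making lab time the
  bottleneck.

Process improvements target the two AF-ablation classes (about 30% of
admissions). For stay phases, a reduction of $x\%$ removes
$\delta = x\% \times \text{LOS mean}$ days from the class's expected stay
— always the full $\delta$ from the LOS mean — while the phase decides
where the days come from: the pre-operative side (mean and truncation
minimum floored at 1 day, any floored remainder implicitly moving to the
post-op side), the post-operative side, or both proportionally. Stay specs
shift as whole distributions: SD fixed, truncation bounds translated with
the mean. Operative-time reductions scale the whole operative distribution
by $1 - x/100$. These choices were made once, on the grounds that (a) the
three phase variants should achieve the same expected LOS reduction,
differing only in scheduling consequences, and (b) translating bounds is
the minimal intervention that actually moves the realized (truncated) mean
by $\delta$ rather than a truncation-diluted fraction of it.

## Randomness and reproducibility

A batch (`run_batch()`) derives one seed per replication from the master
seed by a fixed odd-prime stride modulo $2^{31}-1$, so batches are
bit-reproducible and scenarios run with the same master seed share
per-replication streams (common random numbers at replication
granularity). Within a replication a single stream drives all draws in a
fixed order.

The default calendar starts simulation day 1 on a Sunday. The observation
window's weekday phase shifts replication means by well under the
Monte-Carlo noise; the start weekday is configurable for users who want a
particular alignment.

## Calibration from raw logs

`estimate_config()` turns a patient-log table (one row per patient:
class, admission/discharge dates, and for EP-lab patients the procedure
class/date/times and physician id) into a full configuration: arrival
moments over every calendar day of the log span, per-class duration
summaries, and per-weekday physician allocations from the two most
frequent ids (further ids are folded into the second slot with a warning).
Three inputs are *not* identifiable from such a log and must be supplied:
resource counts, lab clean-up times (not recorded in admission logs), and
the horizon. Physician slot labels are likewise unobservable — only the
unordered pair of allocation probabilities is recovered.

`generate_synthetic_log()` emulates the *input* data a department would
export — it draws from the configured distributions and respects the
admission ≤ procedure ≤ discharge ordering and workday placement — but
deliberately models no resource contention. Round-trip tests
(generate → estimate) therefore demonstrate estimator correctness, not
realism of any particular hospital's records: real logs carry congestion,
seasonality and data-entry noise the generator omits.

## Numerical choices

* Rounding of stays: half up (`floor(x + 0.5)`), stated so tests are
  deterministic; base R's banker's rounding is avoided.
* Truncated sampling by inverse CDF; intervals with mass below $10^{-12}$
  are refused rather than looped on.
* Tie-breaks: physician slot 1 starts first when both slots could start at
  the same instant; labs are taken in index order among equally free ones.
* Zero post-op patients hold their bed until the next morning's turnover.
* A single replication reports an SD of 0 by convention.
* Daily-discharge statistics pool all replication-days; per-replication
  daily means can be formed from the exported per-replication totals.

## Problem sizes

The packaged study runs 1000 replications per scenario (the
`scripts/acceptance.R` reproduction script does exactly that); the test
suite checks the same quantities at 500 replications, at which the
Monte-Carlo standard error of every checked mean is below a quarter of its
tolerance band. One replication simulates roughly 1,200–2,000 patients
over 71 days and takes a few tens of milliseconds.

## Limitations

* The model generalizes one department's two-month observation window;
  seasonality and case-mix drift are outside it.
* Weekend/holiday lab openings, emergency pre-emption, individual
  physician rosters and intra-day bed-cleaning delays are not modelled.
* Reductions apply to whole procedure classes; partial adoption of a
  faster workflow would need a mixing proportion the data did not provide.
* Scenario outputs are means over wide replication distributions; single
  realizations vary substantially (the bed-limited base case has a
  replication SD around 45 discharges).
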