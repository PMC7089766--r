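---
title: "Quantifying TOP2-mediated DSBs from END-seq: models and design choices"
author: "top2dsb maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TOP2-mediated DSBs from END-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(top2dsb)
```

# The biological problem

Topoisomerase II (TOP2) relieves torsional stress by passing one DNA duplex
through a transient double-strand break held together by a covalent
protein–DNA intermediate, the TOP2 cleavage complex (TOP2cc). TOP2 poisons
such as etoposide trap this intermediate. A trapped TOP2cc can follow three
fates: it can *reverse* (re-ligate its break when the drug is removed), it
can remain trapped as an *irreversible* TOP2cc, or the protein can be
proteolytically stripped, leaving a *protein-free DSB* that is handled — and
sometimes resected — by the cellular DSB machinery.

END-seq maps DSB ends genome-wide at single-nucleotide resolution. Two
properties of the protocol carry all the information this package exploits:

* **Exonuclease differential.** Blunting with ExoVII + ExoT detects both
  protein-linked and protein-free DSB ends; blunting with ExoT alone detects
  only protein-free ends. The ExoT / (ExoVII+ExoT) signal ratio at a break
  is therefore the protein-free fraction of its lesions.
* **Washout kinetics.** Sampling before drug washout, immediately after
  (0 hr), and after a 2 hr recovery turns re-ligation and repair into signal
  loss over a timepoint series.

Combined with zinc-finger-nuclease (ZFN) *spike-in* cells mixed into each
library at a known fraction, per-break signal becomes interpretable as the
percentage of cells carrying that lesion.

# Signal model and estimators

## Coverage and RPKM

Aligned read ends are single 1 bp positions (module `coverageFromReads`).
A read at 0-based position $p$ falls in bin $\lfloor p/w \rfloor$ of a
$w$-bp grid; the genome-wide bin sum always equals the library size. Signal
in an interval of length $\ell$ kb from a library of $N$ reads is

$$\mathrm{RPKM} = \frac{\text{reads in interval}}{\ell \cdot N/10^6}.$$

RPKM counts read *ends* inside the interval (END-seq reads mark DNA ends;
fragment overlap would blur the summit). Intervals that do not align to the
bin grid are snapped outward to bin boundaries and the snapped length is
used — at 50 bp bins on 5 kb windows this is a sub-percent effect, identical
across samples, and cancels from every ratio the package reports.

## Spike-in normalization and cell-percentage

With spike-in cells at fraction $f$ of the library (default $f = 0.025$,
the 1:40 ratio), each peak's RPKM is divided by the mean RPKM over the
spike-in break windows and multiplied by $100f$ (2.5 at 1:40):

$$\mathrm{cell\%} = \frac{\mathrm{RPKM_{peak}}}{\overline{\mathrm{RPKM}}_{spike}} \times 100f.$$

Because every spike-in cell carries its break, a peak whose lesion is
present in every cell reads out near 100%. **The peak window and the spike
window must share a width** (both default to summit ± 2500 bp here): RPKM's
per-kilobase factor only cancels from the ratio when the lengths match.
With a 2 kb spike window against a 5 kb peak window the estimate is biased
by exactly the width ratio — we verified a 20%-of-cells truth reading out
as ~8.5% under that mismatch. The mean (not the sum) over spike sites is
used, so the estimator is indifferent to how many spike summits the ZFN
produces; both are exposed as arguments.

## Break detection

Candidate sites (from the simulator truth, a prior run, or any external
peak caller) are kept when

$$\frac{\mathrm{RPKM}_{treated}}{\mathrm{RPKM}_{control} + \epsilon} > 10,$$

with pseudocount $\epsilon = 0.1$ RPKM added to the control only, so sites
with empty control windows are scored rather than dividing by zero. We do
not re-implement a Poisson peak caller: the statistical detection step adds
nothing testable at this package's scope, while the fold filter is the
quantity the downstream break counts depend on.

## Persistence

Per break, persistence at a washout timepoint is the ratio of its signal to
its pre-washout signal in the same treatment arm. Ratios above 1 are
reported unclipped. Sites detected initially but silent later contribute a
ratio of 0 — dropping them would bias persistence upward. The genome-wide
summary is the median with quartiles (a box-plot analog); means are also
reported. Any common scale cancels from the ratio; in practice we feed
spike-normalized cell-percentages, because with desk-scale simulated
libraries the break reads dominate the library and raw-RPKM ratios partially
renormalize toward 1 (composition effect). Real END-seq libraries carry a
large background share which hides this effect, but the spike-normalized
ratio is correct in both regimes.

## Species decomposition

All fractions are expressed relative to the pre-washout ExoVII+ExoT signal,
the initial lesion pool. With $S^{pre}_{VII}$, $S^{0h}_{VII}$ and
$S^{0h}_{T}$ the three required signals at a site:

$$[\mathrm{TOP2cc}]_R = \frac{S^{pre}_{VII} - S^{0h}_{VII}}{S^{pre}_{VII}},
\qquad [\mathrm{DSB}] = \frac{S^{0h}_{T}}{S^{pre}_{VII}}, \qquad
[\mathrm{TOP2cc}]_I = 1 - [\mathrm{DSB}] - [\mathrm{TOP2cc}]_R.$$

Anchoring every fraction to the pre-washout total is the only convention
under which the third identity is a conservation law over the initial
lesion pool. The protein-free numerator is taken at the 0 hr washout
timepoint (reversible complexes have left; what remains is protein-linked
or free), switchable by argument. Sampling noise can push individual ratios
outside $[0,1]$: values are clamped and the triple renormalized to sum
exactly to 1; the clamp count is carried as a QC field on the result.
Genome-wide aggregation either pools signal before taking ratios
(`POOLED`, read-weighted, the default) or averages per-site fractions
(`PER_SITE_MEAN`).

## Resection endpoint caller

For each break and side, fifty 50 bp bins cover the summit out to 2.5 kb
(bin 1 starts at the summit) and fifty more cover 2.5–5 kb. The *background*
is the maximum RPKM over the 2.5–5 kb bins, computed per side (a pooled
two-side background is available by argument). A window of 10 consecutive
bins slides outward one bin at a time; at the first position where more than
half its bins (≥ 6 of 10) are at or below background, the last
above-background bin inside the window marks the **maximum resection
endpoint** (50 bp × bin index). Degenerate cases are resolved as: no
above-background bin in the triggering window → fall back to the last
above-background bin before it, else 0; no window ever triggers → the
endpoint is capped at 2500 bp, the end of the scan. "Above background"
is strict (the rule defines the below-set as "equal to or lower"). Breaks
qualify as resected only when the larger of the two side endpoints exceeds
100 bp. Sites whose summit sits within 5 kb of a chromosome end are skipped
with a warning.

`binProfile` has two routes: from raw read ends (exact, summit-anchored
bins; what the pipeline uses) and from a 50 bp binned track, where the
summit is snapped to the nearest bin boundary (≤ 25 bp shift, below the
one-bin resolution of the caller). In `stranded` mode the left profile uses
minus-strand reads and the right profile plus-strand reads; the default is
unstranded, since whether END-seq resection signal is strand-asymmetric
around the summit is not established — the simulator emits symmetric
stranded tails so both modes are exercisable.

# The synthetic generator

`simulateGenome` places lesion and spike-in summits pairwise ≥ 10 kb apart
and ≥ 5 kb from chromosome ends (a 15 kb grid with < 5 kb jitter enforces
this exactly), so resection flanks never overlap. `simulateSample` draws,
per site and cell, a lesion with probability `p_cleaved` and a species from
the site's `(f_reversible, f_irreversible, f_free)` mixture, then emits a
read end iff the species is observable under the sample's nuclease and
timepoint:

| species      | ExoVII+ExoT                  | ExoT only |
|--------------|------------------------------|-----------|
| reversible   | pre-washout only             | never     |
| irreversible | any timepoint                | never     |
| protein-free | any timepoint                | any timepoint |

At the 2 hr timepoint, surviving (irreversible + free) lesions are thinned
by an extra survival probability (default 0.5) — the data measure, but do
not model, inter-timepoint repair, so this is deliberately the simplest
one-parameter stand-in. Protein-free lesions at washout timepoints are
displaced from the summit by a resection length drawn from an exponential
with mean `resection_mean_bp`, *censored* at `resection_max_bp` (point mass
at the cap, which makes "truth at the cap" exact for recovery tests), on a
uniformly chosen side whose sign sets the read strand. All other emissions
fall within ± 3 bp of the summit (blunting jitter). Spike-in sites emit
from the spike-in cell fraction at full penetrance in every sample and are
never resected. Background reads are uniform at `background_rate` per kb.

Defaults emulate an etoposide arm at desk scale, chosen once: 20% of cells
cleaved per site; species mixture (0.76, 0.04, 0.20); 500 bp mean resection
capped at 2.5 kb; 2000 cells per sample; background 0.05 reads/kb; 20
spike-in summits. The spike count is the one default set by statistics
rather than biology: real ZFN spike coverage is deep enough that
normalization noise is negligible, while at 2000 cells each spike summit
carries only ~50 reads; 20 summits keep the shared (non-averaging)
normalization error near 3% so it does not dominate recovery experiments.

All randomness flows from one integer seed; per-sample seeds are derived
from it and the sample identifier, so samples are independent but each is
reproducible to the byte.

**What the generator does not emulate:** fragment-length structure (reads
are 1 bp ends), sequence context and mappability, copy-number variation,
strand-asymmetric resection, partially proteolyzed intermediates between
intact TOP2cc and protein-free DSB, and library-size renormalization by
sequencing (read counts are per-cell; libraries dominated by break reads
shrink at washout rather than being resequenced to constant depth). Passing
recovery tests therefore demonstrates estimator correctness under the
stated observability model, not robustness to alignment artifacts or
chromatin-driven coverage biases of real data.

# Numerical choices

* Coordinates are 0-based half-open (BED) at every file boundary; GRanges
  (1-based) internally, converted only at I/O.
* bedGraph values are written with 6 significant digits; adjacent bins
  merge only when the formatted values are exactly equal; zero bins are
  omitted.
* Species fractions: clamp to $[0,1]$, then renormalize; equality to 1 is
  then exact up to machine epsilon and asserted at 1e-9.
* Endpoint scan: stride 1 bin; "more than half" of a 10-bin window means
  ≥ 6 (exactly 5 does not trigger); the scan is invariant to common
  positive scaling of bins and background.
* Sites with zero pre-washout signal are excluded from ratios with a
  warning; zero-control detection windows are handled by the pseudocount,
  never by dropping the site.
* Truth tables round-trip through 6-decimal text; the reader renormalizes
  the species mixture (tolerance 1e-4) so the sum-to-1 invariant survives
  rounding exactly.

# Study conditions used by the shipped checks

The test suite and `scripts/acceptance.R` regenerate everything they
measure. Problem sizes are chosen for fast, stable recovery: 200 sites ×
2000 cells (species fractions, ± 0.03); 50 sites × 600 cells per fixed
resection length in {200, 600, 1200} bp (≥ 95% of endpoints within one
bin); 100 sites × 2000 cells for persistence against a 0.3 survival truth
(three standard errors, including the shared spike-normalization term);
1000 random bin vectors against a brute-force window enumerator. The
detection-retention check runs on a 10 Mb genome with background 1 read/kb:
fold-enrichment detection needs a background-dominated control and
enrichment headroom (genome size / (sites × window) well above the
threshold) to be informative — with tiny site-dominated libraries, RPKM's
composition renormalization makes per-site fold nearly independent of
survival, which is a property of the metric, not a bug of the detector.

# Known limitations

* The fold-enrichment detector assumes candidate summits are given; it is
  not a de novo peak caller.
* Cell-percentage accuracy is bounded by spike-in coverage; with few spike
  reads the shared normalization error does not average away across sites.
* The 2 hr washout survival parameter is phenomenological; no repair
  kinetics are modeled.
* Persistence compares independent libraries per timepoint; biological
  replicate structure (the reference-replicate convention for peak sets) is
  the caller's responsibility via the sample sheet.
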