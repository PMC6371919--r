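---
title: "Methods: calibrated ChIP-seq processing and the ring-entrapment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated ChIP-seq processing and the ring-entrapment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesintools)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, and the
numerical conventions chosen where the underlying experimental procedures
leave them open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Spike-in calibrated ChIP-seq

### The measurement problem

ChIP-seq read densities are only proportional to occupancy *within* one
library; library size, IP efficiency and sequencing depth differ between
samples, so raw tracks from two strains cannot be compared height-to-height.
Spike-in calibration fixes this by mixing a constant ratio of calibration
cells (a diverged relative whose reads can be told apart by alignment) into
every sample before crosslinking. Reads are then partitioned between the two
genomes, and the occupancy ratio

$$\mathrm{OR} = \frac{W_c \cdot IP_x}{W_x \cdot IP_c}$$

— computed from WCE (input) and IP read counts on the experimental ($x$) and
calibration ($c$) genomes — converts raw depth to a common scale. Intuitively
the WCE counts estimate the true genome mixing proportion and the IP counts
measure how strongly each genome's chromatin was pulled down relative to it.
OR is a ratio of ratios, so it is invariant to multiplying all four counts by
any constant (sequencing deeper changes nothing), which the test suite
asserts directly.

### Sequential read assignment

Reads are assigned in the same order a sequential alignment pipeline would:
against the calibration genome first, the unaligned leftovers against the
experimental genome. Our internal mapper is **exact-match over both
strands** with a uniqueness requirement: a read is assigned iff it matches
exactly one location in the genome under test (reverse-strand matches are
reported at the leftmost forward-coordinate base, as in SAM). This is the
correct desk-scale surrogate for "uniquely aligning" reads because the
synthetic genomes guarantee every read-length k-mer occurs at most once
across both strands of both genomes, and the simulated reads are error-free.
On such inputs assignment provably recovers the true origin of every read,
and the test suite checks agreement with an exhaustive position-by-position
scanning oracle.

Two conventions are worth flagging:

* A read that matches the calibration genome at *several* locations is still
  tested against the experimental genome. A real aligner would have reported
  a multi-mapping calibration alignment and retained the read on the
  calibration side; we follow the stricter unique-hits-only contract
  throughout. With valid genome pairs the case cannot arise at the guaranteed
  read length.
* Externally produced alignments are accepted through
  `read_sam_assignments()`, which treats records below a MAPQ floor
  (default 10) as unassigned. Published pipelines rarely state this
  threshold; it is a configurable parameter, not an asserted value.

### Pileups, meta-profiles and calibration

`zero_filled_pileup()` computes per-base read depth with every position of
the chromosome present (gap positions at depth 0). "Reads at each base
pair" is implemented as *coverage* (mpileup semantics: a read covers all the
bases of its aligned interval), not read-start counts.

`anchor_meta_profile()` averages depth at each signed offset
$d \in [-W, +W]$ from a per-chromosome anchor — the CDEIII-like centromere
element — across chromosomes. Two conventions:

* **Anchors are single base pairs** at offset 0, although the real element
  has finite width; with W of tens of kb the difference is invisible.
* **Truncated windows are excluded, not zero-padded**: a chromosome whose
  anchor sits closer than W to an end contributes only to the offsets its
  coordinates cover, and `n_contributing` records how many chromosomes enter
  each mean. Zero-padding would bias flank averages downward near ends.

Calibration multiplies every value by $\mathrm{OR} \times 10^6 / IP_x$.
The per-million denominator is the count of uniquely assigned
experimental-genome IP reads by default; since descriptions of
"normalized to 1 million reads" rarely say which total, the alternative
(all uniquely assigned IP reads) is available via
`occupancy_ratio(..., denominator = "all")`. Both calibration factors are
multiplicative, so the order (average, then OR, then per-million) does not
affect the result. A `state` flag on tracks and profiles makes calibrating
twice an error rather than a silent double scaling.

A useful exactness property falls out of the floating-point structure:
duplicating every input read doubles all depths and `IP_x` while leaving OR
unchanged, and because the per-million factor is divided by an exactly
doubled integer, the calibrated profile is *bit-identical*, not merely close.
The acceptance suite asserts `identical()`, not `all.equal()`.

Tracks export as bedGraph (0-based half-open, equal-value runs collapsed) or
`fixedStep` wiggle text — the text stand-ins for binary BigWig. Values are
printed with `%.17g`, which round-trips IEEE doubles exactly; the parser is
the inverse and the round trip is tested on calibrated (non-integer) tracks.

## 2. The synthetic-data generator

The generator's defaults *are* the study conditions the analysis targets:

| parameter | default | rationale |
|---|---|---|
| cell ratio (exp:cal) | 3:1 | 15 OD of experimental cells mixed with 5 OD of spike-in cells |
| `decay_span` | 30 000 bp | centromere-loaded cohesin spreads up to ~30 kb into peri-centric sequences |
| `peak_enrichment` | 10× | strong centromeric enrichment over arm background |
| read length | 50 bp | keeps toy genomes (≤ 200 kb) uniquely mappable; real reads are longer |
| anchors | chromosome midpoints | genome-specific CDEIII coordinates are out of scope |
| calibration IP profile | uniform background | no enrichment structure is modelled for spike-in chromatin; an assumption, not an inference |
| interval / duration (ATPase) | 0.5 / 90 min | absorbance read every 30 s for 90 min |
| `e = (0.6, 0.6, 0.6)` | per-interface crosslink efficiency | gives full-ring closure of 0.216, inside the observed 20–25% circularization band |
| `p_CM = p_CD = 0.3` | detection fractions | absolute detectability is never measured; only ratios enter any asserted statistic, so a mid-range value is used once and not revisited |
| gel noise | multiplicative log-normal, `sdlog = noise_sd` | band intensities are positive and errors scale with signal; only means ± SD are ever reported for real gels |

Enrichment decays *linearly* from the anchor to background over
`decay_span`; no functional form is established experimentally, and a
triangle is the simplest shape with a well-defined span. IP start positions
are weighted by the profile evaluated at the **read midpoint**, so the depth
peak (what a browser shows) is centred on the anchor rather than shifted by
half a read length. WCE sampling gives every valid start position equal
weight (`cell_ratio` per experimental start vs 1 per calibration start), so
genome shares are proportional to cell ratio × (L − k + 1) — at desk scale
indistinguishable from genome length, and exactly the closed-form binomial
when lengths are equal.

What the generator deliberately does **not** emulate: sequencing errors,
quality variation, paired ends, PCR duplicates, chromatin fragment-size
distributions, mappability structure of real genomes, or enrichment of
spike-in chromatin. Passing tests therefore demonstrate the correctness of
the *computations* (assignment logic, counting, averaging, scaling, the
combinatorics) on idealized reads — they do not validate robustness to
alignment artifacts or library-preparation biases in real data.

## 3. The ring-entrapment stoichiometry model

### Model

A strain expresses $n$ cohesin copies; copy $i$ carries cysteine pairs at a
subset of the three ring interfaces (hinge, Smc3–kleisin, kleisin–Smc1) and
may carry the IP epitope tag. Crosslinking events are independent across
interfaces and copies (no cooperativity term), so a copy fully circularizes
with probability

$$c_i = \prod_{j \in \text{interfaces}(i)} e_j
  \quad\text{if all three interfaces are paired, else } 0 .$$

A catenated monomer (CM) requires a circularized *tagged* ring:
$\mathrm{CM} = p_{CM}\, \bar c_{\text{tagged}}$. A cohesive unit consists of
$k$ rings — $k = 1$ is the ring model, $k \ge 2$ the handcuff/oligomer
model. Detection of a catenated dimer (CD) requires **every** member ring
to be circularized (covalent catenation of the dimer requires all rings
closed), and the IP conditions on the tagged copy being a member:

$$\mathrm{CD} = p_{CD}\; c_{\text{tagged}}\; m^{\,k-1},
  \qquad m = \tfrac1n \sum_i c_i .$$

Partner rings are drawn **uniformly with replacement** from the expressed
pool — the upper-bound reading of the "one quarter *(or less)*" prediction;
preferential pairing would only lower the mixed-design CD fraction. Whether
the untagged partners of a tagged unit also need tags is not determined
experimentally; we implement any-member-tagged (IP pulls the whole unit),
and flag it as an assumption. Band intensity is treated as linear in
molecule count, as percentage-of-lane densitometry already assumes.

For the tetraploid design pair (4×6C control vs 1×6C+3×5C test, equal
efficiencies), $c_{\text{tagged}}$ and therefore CM are identical, while
$m$ drops fourfold, giving the test statistic

$$\frac{(\mathrm{CD}/\mathrm{CM})_{\text{4×6C}}}
        {(\mathrm{CD}/\mathrm{CM})_{\text{1×6C+3×5C}}} = 4^{\,k-1}$$

— identically 1 under $k=1$ for *any* composition and efficiencies (a
property the suite verifies over random models), 4 under $k=2$, 16 under
$k=3$. The closed forms are verified against exhaustive enumeration over
all $2^{3n}$ crosslink outcomes and all $n^{k-1}$ ordered partner tuples.

### Classification

`classify_stoichiometry()` turns the verbal inference into a decision rule:
$z_k = |\text{observed} - 4^{k-1}| / \mathrm{SD}$, smallest $z$ wins, ties
break toward smaller $k$ (parsimony) and are flagged. Because the SD is a
common factor, classification reduces to nearest-prediction; the SD is kept
in the interface so the $z$ values are interpretable as significance
measures. With predictions 1 and 4 the decision boundary sits at 2.5, far
outside the spread of 3-replicate experiments at realistic (≤ 15%) gel
noise, which is why simulated experiments classify correctly in ≥ 95% of
trials.

## 4. ATPase quantification

The phosphate standard curve is an ordinary least-squares line
(AU = slope·µM + intercept) with its RMS residual reported; a fit requires
two distinct concentrations, and equal concentrations raise a
"degenerate curve" error. The hydrolysis rate is the OLS slope of
absorbance against time over the **fixed window \[0, 10\] min** — the linear
phase convention — divided by the curve slope, reported in µM
phosphate/min with the window fit's $r^2$. No automatic linear-phase
detector is attempted (none is described for this assay); the window length
is a parameter, and the $r^2$ lets the user notice saturation intruding
into the window. At least 3 points must fall inside the window. Optional
baseline subtraction (a no-protein control series) is available but off by
default, since it is not established whether published rates were
background-subtracted. Conversion to per-complex turnover is left to the
caller via their complex concentration (assays of this kind use ~50 nM
tetramer); the package does not hard-code it.

The simulate-then-estimate round trip is exact at zero noise (the windowed
points are exactly collinear) and within three standard errors under
additive noise, checked over 100 seeded trials.

## 5. Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive internally (SAM convention); BED and
  bedGraph output converts to 0-based half-open.
* `occupancy_ratio()` refuses zero denominators, naming the offending count
  (`W_x` or `IP_c`); zero *numerators* are not errors at construction but
  produce OR = 0, which downstream constructors reject.
* Pileup intervals exceeding chromosome bounds are a hard error (they can
  only arise from an upstream invariant violation), whereas a *read longer
  than any chromosome* is merely unassigned with a warning — malformed
  input, not pipeline corruption.
* `replicate_stats()` uses the sample SD (n−1) and reports `NA`, not 0, for
  a single lane; a lane of all-zero bands is an "empty lane" error.
* Genome generation retries up to 20 times to satisfy k-mer uniqueness and
  then fails with "genome too repetitive" (with 50-mers over ≤ 200 kb the
  first draw virtually always succeeds; 1-mers can never succeed).
* All simulators take an explicit integer seed, restore the caller's RNG
  state, and are byte-reproducible: same arguments + seed, same output,
  including on-disk FASTA/FASTQ/BED.

## 6. Problem sizes used by the test suite

The suite is sized to run comfortably on one CPU in a few minutes: shared
fixtures use 2 × 3 kb experimental + 2 kb calibration genomes with 40 bp
reads; the enrichment-recovery check uses 2 × 100 kb + 20 kb genomes with
100 000 IP reads (flank measured beyond the 30 kb decay span, anchor over
±250 bp, agreement within 15%); lane-model statistics use 1000 simulated
3-replicate experiments; brute-force oracle comparisons run 200 randomized
cases per operation at ≤ 2 kb. These sizes are the package's choices for a
desk-scale demonstration — real experiments involve 12 Mb genomes and
millions of reads, which change nothing in the algorithms but are not
needed to establish their correctness.

## 7. Known limitations

* The exact-match mapper is not an aligner: no mismatches, gaps or quality
  awareness. Real data should be aligned externally and ingested as SAM.
* The entrapment model treats crosslinking as independent Bernoulli events
  and band intensity as linear; nicked/relaxed topoisomers, 2D-gel
  behaviour and crosslinker toxicity are out of scope.
* The uniform-partner-draw handcuff model is the upper bound contemplated
  by "one quarter (or less)"; non-uniform pairing or $k > 2$ oligomers are
  representable (any `k`, any composition) but only the uniform case is
  asserted against.
* WCE tracks can be profiled with the same machinery, but no quantitative
  claims are made about them (IP profiles are the calibrated quantity).
* Absolute `p_CM`/`p_CD` are not inferable from this assay; only
  ratio-based statistics should be interpreted.
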