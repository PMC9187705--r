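---
title: "Inferring replication timing profiles from S/G1 sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring replication timing profiles from S/G1 sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement

DNA replication follows a reproducible temporal program: some loci
replicate early in S phase, others late. In an asynchronous culture sorted
by DNA content, S-phase cells have partially duplicated genomes, and a
locus replicating at time $\tau \in [0,1]$ (as a fraction of S phase) has
been duplicated in a fraction $1-\tau$ of S-phase cells. Sequencing
coverage in the S fraction is therefore proportional to an expected copy
number between 1 and 2, highest at early-replicating loci, while the
G1 fraction provides a uniform two-copy baseline that carries all the
non-replication structure (mappability, GC bias, copy-number variants).
The S/G1 coverage ratio isolates replication timing.

`rtprofiler` turns aligned read start positions from a G1 and an S library
into a normalized replication timing (RT) profile in three steps:

1. **Uniform-coverage binning.** Each chromosome is cut into variable-size
   bins containing exactly `reads_per_bin` (default 200) G1 read starts.
   Bin boundaries sit at the midpoint between the last read of one bin and
   the first read of the next; a trailing remainder of fewer than 200
   reads is dropped; chromosomes with fewer than 200 reads are skipped.
   Because a region with doubled G1 density receives half-width bins, the
   per-bin S/G1 ratio is automatically insensitive to CNVs and mappability
   structure — this is the method's bias correction, and no separate
   CNV-calling stage exists. The per-bin ratio is library-size normalized:
   $r_j = (s_j/\sum s)/(g_j/\sum g)$.

2. **Cubic smoothing-spline smoothing.** The raw ratio is smoothed per
   gap-free segment by the natural cubic smoothing spline minimizing
   $p\sum_j (r_j - f(x_j))^2 + (1-p)\int f''(t)^2\,dt$ with unit weights
   and $x$ in **bp** — the `csaps` convention. Both the parameter
   ($p = 10^{-16}$ by default) and the unit of $x$ matter: the penalty
   integral scales as $x^{-3}$, so the same $p$ with $x$ in, say, Mb would
   smooth $10^{18}$ times harder. At 200-read bins and typical desk-scale
   depths (20-kb bins) this $p$ corresponds to an equivalent-kernel
   bandwidth of roughly 100 kb. The solver is the Reinsch algorithm (a
   sparse pentadiagonal solve), whose $p \to 1$ limit is exact
   interpolation and whose $p \to 0$ limit is the least-squares straight
   line; both limits are tested, and mid-range values are verified against
   `stats::smooth.spline` with the analytically mapped
   $\lambda = (1-p)/(p\,r^3)$ (range-scaled domain, all knots).

3. **Autosome-anchored normalization.** Smoothed values are z-scored with
   the unweighted mean and SD of *autosomal* bins, so autosomes have mean
   0 and SD 1 exactly; positive rt is early. chrX is scaled with the
   autosomal statistics but not recentred (an XX-late X territory keeps
   its shift); chrY is dropped entirely.

Segments are defined by bin-center gaps larger than `max_gap` (default
100 kb): assembly gaps such as rDNA placeholders produce read voids, bins
spanning them become very wide, and smoothing must not bridge them.
Segments shorter than 4 bins pass through unsmoothed with a warning.
Normalization statistics are computed on smoothed values (the profile is
normalized after smoothing); per-bin values are unweighted since bins hold
near-identical G1 coverage by construction.

## Downstream statistics

**Peaks, inter-origin distances, slopes.** Local maxima of the smoothed
profile proxy replication initiation zones. Extrema are discrete
neighbor-comparisons over bin centers within a segment, with plateaus
collapsed to their midpoint bin; peaks and valleys alternate. An optional
prominence filter (`min_prominence`, z-units, default 0) iteratively
removes shallow extrema and re-enforces alternation by discarding the
shallower of any adjacent same-kind pair. Distances between consecutive
peaks in a segment proxy inter-origin distance; a distance is attributed
to a region set only when *both* peaks lie inside it, and "rest of the
genome" is the complement of the centromeric region set. Each peak's slope
is the mean of its ascending and descending flanks (|Δrt| / Δpos, z-units
per Mb) against its neighboring valleys, falling back to the segment
boundary bin where a flank valley is missing.

**Satellite families.** A cenSat-style BED9 annotation is mapped to
canonical families (hor, dhor, mon, hsat1–3, bsat, gsat, ct, rDNA,
censat_other) by case-insensitive name-prefix matching; the table is
overridable because track vocabularies drift. Each profile bin is assigned
to the family covering its *center* (half-open; bins are tens of kb
against multi-Mb arrays, so center assignment and overlap-majority agree
almost everywhere); the annotation must partition the genome, and
statistics are per-bin (not bp-weighted). Reported per family: median,
IQR, early fraction (rt > 0), bin count, against a configurable baseline
subset (default: all non-centromeric bins).

**Cross-assembly comparison.** UCSC chain files are parsed with strict
block arithmetic validation. Fixed-width windows map through the single
highest-scoring overlapping chain iff ≥ `min_match` (default 0.95) of
their bases fall in aligned blocks; negative-strand query coordinates are
converted to forward strand. This is deliberately simpler than liftOver's
multi-chain behavior, so mapped fractions are comparable to published
liftOver percentages only up to dialect. Unmapped reasons: `no_chain`,
`partial`, and `split` — the last defined here as "enough aligned bases,
but the query span is inconsistent with a single interval" (span minus
aligned bases exceeding the unaligned allowance). Profiles are compared by
Pearson correlation of nearest-bin rt values at mapped window midpoints.

**Centromere rankings.** Each region's interior is divided into 100
equally spaced relative bins; the 5-Mb flanks use fixed 50-kb bins (the
interior is length-normalized across chromosomes, the flanks are not).
Relative bins without data are missing, never zero. Per chromosome,
samples are ranked by descending median rt over the region's interior bins
(rank 1 = earliest; medians are per-bin, flanks excluded); ties are broken
lexicographically and flagged, and rank counts per sample sum to the
number of scored chromosomes.

## The synthetic world

The generator gives every stage an analytic ground truth. A `landscape`
fixes origin positions, firing times $t_i$ (fractions of S phase) and a
constant speed $v$ (bp per unit S phase) for the timing front, so
$\tau(x) = \min_i\, t_i + |x - x_i|/v$, capped at 1. S-phase cells are
taken uniformly through S — the simplest generative model consistent with
S/G1 logic — making expected copy number affine: $c(x) = 2 - \tau(x)$,
which is what makes the generator analytically checkable. Reads are
single start positions drawn multinomially with per-bp weight `bias` (G1)
or `bias × c(x)` (S), evaluated on 1-kb tiles and uniform within tiles;
gaps emit zero reads in both phases, emulating rDNA placeholders. Not
modeled: stochastic per-cell firing, fork stalling, sister-chromatid
asymmetry, fragment lengths, GC-dependent error. A green test therefore
establishes the pipeline's correctness on an idealized kinetic world, not
robustness to those real-data features.

### The benchmark world and its parameters

The parameter-recovery benchmark (100 Mb, 50 origins, $10^6$ reads per
phase) must be *identifiable*: every origin should fire actively (an
origin passively replicated by a neighbor's fork leaves no timing peak,
making "recovery" ill-posed) and $\tau$ should complete within S phase
(capped $\tau = 1$ plateaus carry no rank information). With mean spacing
fixed at 2 Mb by the benchmark itself, this forces the stated world:

* `min_origin_gap = 1.9 Mb` — near-regular strong initiation zones;
  origin positions are otherwise uniform (drawn exactly by the
  shrink-and-expand construction).
* `firing_range = [0, 0.2]` — with spacing/v ≈ 2, no firing-time
  difference can exceed the fork travel time, so all origins fire.
* `fork_speed = 1e6` bp per unit S phase — at the timing-front level this
  is the *effective* migration speed between peaks and valleys, faster
  than single measured forks (~1–2 kb/min) because initiation zones fire
  dispersedly; slower fronts would leave mid-gap loci unreplicated at the
  stated spacing, faster ones flatten the profile into noise.

Under this world ~11% of loci still cap at $\tau = 1$, which is why the
rank correlation between −rt and $\tau$ plateaus near 0.99 rather than 1.

### A known limitation: peak localization at desk-scale depth

Peak *positions* carry an irreducible jitter. A 200-read bin has ratio
CV ≈ $\sqrt{2/200} \approx 10\%$ (Poisson S counts plus Gamma-distributed
G1 bin widths); the $p=10^{-16}$ spline at 20-kb bin spacing averages
roughly a 120-kb equivalent kernel; propagating the smoothed noise
gradient against the tent-apex curvature gives a peak-location SD of
25–30 kb at fork speed $10^6$. The fraction of well-separated origins
recovered within ±2 bin widths (±40 kb) is therefore ~0.8 at $10^6$
reads/phase, and the package's acceptance suite asserts the 0.90 target
and *fails it* deliberately rather than widening the tolerance; roughly
4× the read depth, or steeper profiles than a completing S phase allows,
would be needed to reach 0.90. Peak *counts* and inter-peak distance
medians are unaffected (measured within 2% of truth), as is the rank
correlation.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; a read exactly at a bin
  end belongs to the next bin; a bin center exactly on an annotation
  boundary belongs to the interval starting there.
* Bin boundaries round up (`ceiling`) so the earlier read stays inside
  its bin; coincident boundary reads place the boundary just after them.
  Duplicate read positions are retained (no dedup) — the least
  destructive default, logged as policy.
* The spline solve guards: non-increasing x and $p \notin (0,1)$ are
  errors; < 4 points pass through with a warning; non-finite results
  abort.
* Normalization requires ≥ 2 autosomal bins and positive autosomal SD
  ("degenerate profile" otherwise).
* bedGraph output is fixed 6-decimal; write-then-read reproduces values
  to 1e-6 and byte-identical reruns are tested.
* Ranking ties are resolved lexicographically *and* flagged — real data
  is expected tie-free, simulations with shared seeds are not.

## What the acceptance surface establishes

`scripts/acceptance.R --seed N --out f.json` recomputes, from scratch:
the normalization contract (autosomal mean/SD exact to 1e-9), the bin
contract (exact 200-read bins; S-count conservation), the benchmark
recovery triple (origin recovery — the documented red; Spearman; distance
ratio), the three spline limits, chain identity/gap mapping with exact
mapped+unmapped accounting, and the 3-sample centromere ranking recovery
(≥ 20 of 22 chromosomes). Published statistics from real data (medians of
0.5–0.65 Mb and ~0.9 z/Mb, cross-build r > 0.999, ~6% non-liftable
windows, satellite medians) require the original sequencing libraries
realigned to a T2T assembly; the pipeline emits each of those statistics
so they can be checked when such data are available, but none is asserted
against here.
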