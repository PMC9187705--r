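# rtprofiler

Replication timing (RT) profiles from S/G1 whole-genome sequencing, with
the downstream statistics used to study replication of centromeres and
satellite DNA, and a synthetic replication-kinetics generator that gives
every stage an analytic ground truth.

## The method

Sorted S-phase cells over-represent early-replicating loci: a locus
replicating at time τ (fraction of S phase) has expected copy number
c = 2 − τ, while G1 cells are a uniform two-copy baseline carrying all
non-replication structure (mappability, GC, CNVs). `rtprofiler` infers RT
as:

1. **Variable-size bins of uniform G1 coverage** — exactly 200 G1 read
   starts per bin, boundaries at read midpoints; the S/G1 ratio per bin
   r_j = (s_j/Σs)/(g_j/Σg) is then intrinsically bias- and CNV-corrected.
2. **Cubic smoothing spline** in the csaps convention,
   p·Σ(r_j − f(x_j))² + (1−p)·∫f″(t)²dt with x in bp and p = 1e-16,
   applied per gap-free segment (segments split at >100 kb bin-center
   gaps, e.g. across rDNA voids).
3. **Normalization** to autosomal mean 0 and SD 1 (positive rt = early);
   chrX is scaled but not recentred, chrY dropped.

On top of the profile: peak/valley calling with prominence filtering,
inter-peak distances (a proxy for inter-origin distance) and peak slopes
(z/Mb, a proxy for fork speed) by region; satellite-family RT bias from
cenSat-style annotations; cross-assembly window mapping through UCSC
chain files with profile correlation; and per-chromosome earliest-to-
latest sample rankings over centromeric regions.

## Worked example

```r
library(rtprofiler)
set.seed(42)

# a 20 Mb toy genome: 4 chromosomes, origins every ~2 Mb
lss <- sim_genome_landscapes(n_chrom = 4, chrom_length = 5e6,
                             origins_per_chrom = 3, fork_speed = 1e6,
                             firing_range = c(0, 0.2), min_origin_gap = 1.5e6)
reads <- simulate_experiment(lss, n_reads_g1 = 2e5, n_reads_s = 2e5, seed = 42)

prof <- rt_pipeline(reads$g1, reads$s, reads_per_bin = 200)
prof[1:3, c("chrom", "start", "end", "raw_ratio", "rt")]
#>   chrom start   end raw_ratio     rt
#> 1  chr1    23 17645     0.820 -0.528
#> 2  chr1 17645 37476     0.980 -0.435
#> 3  chr1 37476 55858     0.835 -0.340

dyn <- replication_dynamics(prof)
```

Printed by the run above:

```
bins: 998   autosomal mean rt: 4.18e-16   sd: 1.000000
peaks called: 12   median inter-peak distance: 1.59 Mb   median slope: 2.59 z/Mb
true median inter-origin spacing: 2.05 Mb
Spearman rho(-rt, true tau): 0.991
```

998 bins of ~20 kb each carry exactly 200 G1 reads; the normalized
autosomal profile has mean 0 and SD 1 by construction. All 12 simulated
origins are called as peaks; with only eight within-chromosome peak pairs
the toy's distance median is noisy (1.59 vs 2.05 Mb true) — the 100-Mb
benchmark in the acceptance suite pins it within 2%. The rank correlation
of −rt with the true replication time τ is 0.991.

A file-based workflow is available through the CLI front end
(`inst/scripts/rtprofiler` or `rtprofiler_cli()`): subcommands `simulate`,
`bin`, `profile`, `dynamics`, `satstats`, `cenrank`, `liftcompare`, all
reading/writing plain BED/bedGraph/TSV/JSON.

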