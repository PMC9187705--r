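Package: rtprofiler
Title: Replication Timing Profiles from S/G1 Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("rtprofiler", "developers", email = "rtprofiler@example.org",
           role = c("aut", "cre"))
Description: Infers DNA replication timing (RT) profiles from aligned read
    start positions of G1-phase and S-phase sequencing libraries using the
    S/G1 method: variable-size genomic bins of uniform G1 coverage, cubic
    smoothing-spline smoothing, and normalization to an autosomal mean of 0
    and standard deviation of 1. Includes downstream analyses (RT peak
    calling, inter-origin distances and slopes, satellite-family RT bias,
    cross-assembly profile comparison through UCSC chain files, and
    cross-sample centromere rankings) and a synthetic replication-kinetics
    read generator that provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
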