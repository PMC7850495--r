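# msiskew

Tumor-only microsatellite instability (MSI) calling from targeted
sequencing, using the skewness of per-marker read-length distributions.
No matched normal, no baseline cohort.

## The science

Microsatellites — tandem repeats of 1–6 bp motifs — drift in length when
DNA mismatch repair fails, producing the MSI-high (MSI-H) phenotype that
guides prognosis and immunotherapy in colorectal and other cancers. At a
stable locus, sequencing reads form a tight, symmetric length distribution
around the reference tract length. At an unstable locus in an impure
tumor, the reads are a mixture of reference-length molecules (normal cells
and the unmutated allele) and contracted molecules (the mutant allele) —
an *asymmetric* distribution. Asymmetry needs no reference cohort to
measure.

For each marker, every spanning read's repeat-tract length is extracted by
a CIGAR walk and normalized against the reference (`delta = observed −
reference`). The per-marker statistic is Pearson's skewness coefficient

```
PSC = 3 · (mean(delta) − median(delta)) / sd(delta),    PSC ∈ [−3, 3]
```

and the decision rules are:

* markers with coverage ≤ 20× are filtered out (not scored);
* a valid marker is **unstable** when |PSC| > 1 (strict);
* a sample is **MSI-H** when the fraction of unstable markers among valid
  markers reaches the tissue-type cutoff (inclusive): **0.4** for fresh
  tissue and cell lines, **0.25** for FFPE tissue.

The package also ships a seeded cohort simulator (PCR stutter, contracted
tumor allele, FFPE coverage dispersion/dropout/artifact noise) that can
emit length tables or toy SAM + FASTA with per-read ground truth, and an
evaluation harness (confusion metrics, paired McNemar test). See the
methods vignette (`vignettes/msiskew-methods.Rmd`) for the model, the
parameter semantics and the design choices.

## Worked example

Simulate a small fresh-tissue cohort over the packaged 23-marker panel,
call every sample, and score the calls against the simulator's truth:

```r
library(msiskew)

panel <- readMarkerPanel(system.file("extdata", "panel23.tsv",
                                     package = "msiskew"))
panel
#> MarkerPanel 'panel23' with 23 markers
#>   repeat units: 1bp x22, 2bp x1
#>   tract lengths: 7-44 bp

cohort <- simulateCohort(panel, SimParams(seed = 7, n_msih = 2, n_mss = 3,
                                          sample_type = "fresh"))

x <- cohortSamples(cohort)[["msih_001"]]
calls <- callMarkers(x)              # per-marker PSC + instability
head(as.data.frame(calls), 4)
#>     marker_id coverage       psc valid unstable
#> 1       BAT40      113  0.000000  TRUE    FALSE
#> 2    AIM2-A10      122 -1.887383  TRUE     TRUE
#> 3   TCF7L2-A9       96 -2.442132  TRUE     TRUE
#> 4 SLC22A9-T11      122 -0.365610  TRUE    FALSE

classifySample(calls, sample_id = "msih_001", sample_type = "fresh")
#> SampleResult 'msih_001' (fresh): MSI-H
#>   unstable 14 / valid 23 of 23 markers (fraction 0.609, cutoff 0.40)
```

The negative PSC values reflect the deletion bias of MSI: the contracted
allele drags the mean below the median. 14 of 23 valid markers are
unstable, so the fraction 0.609 clears the fresh-tissue cutoff 0.4 and
the sample is MSI-H. Over the whole cohort:

```r
tab <- classifyCohort(cohort)
tab
#>   sample_id truth n_valid n_unstable unstable_fraction status
#> 1  msih_001 MSI-H      23         14         0.6086957  MSI-H
#> 2  msih_002 MSI-H      23         14         0.6086957  MSI-H
#> 3   mss_001   MSS      23          0         0.0000000    MSS
#> 4   mss_002   MSS      23          0         0.0000000    MSS
#> 5   mss_003   MSS      23          0         0.0000000    MSS

msiConfusion(truthStatus(cohort), setNames(tab$status, tab$sample_id))
#> $tp [1] 2 ... $sensitivity [1] 1  $specificity [1] 1  $accuracy [1] 1
```

Real alignments enter through `collectLengthDistributions("tumor.bam",
panel)` (SAM or BAM); plain length-table TSVs are accepted everywhere a
BAM is (`readLengthTable()` / `writeLengthTable()`), so the statistical
pipeline runs without alignment files.

A command-line wrapper with `panel` / `extract` / `call` / `simulate` /
`evaluate` subcommands is installed at
`system.file("scripts", "msiskew.R", package = "msiskew")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","msiskew.R",package="msiskew"))')" \
    call --lengths sample.lengths.tsv --panel panel23.tsv \
    --sample-type ffpe --out-prefix sample
```

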