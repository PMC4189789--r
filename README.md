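# barrelgap

Tools for quantifying whisker-mediated touch in mice on two complementary
readouts:

1. **Cortical**: per-pixel Fourier extraction of the stimulus-locked
   fractional reflectance change (ΔR/R) from intrinsic-signal optical
   imaging (OIS) of barrel cortex under periodic whisker stimulation, with
   threshold-curve quantification of the responsive region and a two-way
   ANOVA genotype comparison of region size.
2. **Behavioral**: a discrete-event reimplementation of the closed-loop
   gap-cross assay — the exploration/adjustment state machine, four-sensor
   trial classification, and the adaptive gap-distance algorithm — plus the
   session-block learning statistics (block × distance repeated-measures
   ANOVA within genotype; between-genotype improvement t-test).

It is aimed at researchers who run temporally-encoded imaging or
gap-cross-style adaptive behavioral assays and want a tested, scriptable
reference for the analysis, and at anyone who needs a fully synthetic
test bed: the package ships generative stand-ins (an imaging phantom and a
behavioral agent) with exactly known ground truth, so the entire pipeline
is verifiable without animal data.

## The core computations

**Fourier readout.** With stimulation repeating at $f_s$ (e.g. every 20 s,
$f_s = 0.05$ Hz) and a pixel series $x_t$, $t=0,\dots,n-1$, the response is

$$\widehat{\Delta R/R}=\frac{2\,|X(f_s)|}{n\,\bar x},\qquad
X(f_s)=\sum_t (x_t-\bar x)\,e^{-2\pi i f_s t/f_r},$$

the fractional amplitude of the stimulus-locked sinusoid at each pixel
(phase is $\arg X$). The acquisition must span whole stimulus periods so
$f_s$ sits on an exact Fourier bin; off-bin protocols are rejected rather
than leaked. The responsive region is summarised as the number of pixels
with ΔR/R above each value of an ascending threshold grid.

**Adaptive distance algorithm.** Each next gap distance is drawn uniformly
from the 0.5 cm grid spanning 1.0 cm below to 1.5 cm above the session's
maximum successfully crossed distance, clamped to [3.0, 7.0] cm; sessions
open at 3.0 cm and run to 20 successes or 20 minutes, 12 sessions per
experiment.

**Learning statistics.** Percent successful crossings per mouse × distance
× session block (1–6 vs 7–12), block effects tested by repeated-measures
ANOVA with mouse-by-distance cells as matched subjects
(block $F(1,\,k(n-1))$ for $n$ mice, $k$ distances), and nose (≤ 4.5 cm)
versus whisker (≥ 5.0 cm) improvement compared between genotypes by
two-tailed t-test.

See `vignettes/barrelgap-methods.Rmd` for the models, parameter defaults
and design decisions.

## Worked example

```r
library(barrelgap)

## --- imaging: phantom stack -> response map -> threshold curve
cfg  <- ois_phantom_config(seed = 42)       # 64x64, 700 frames, 0.05 Hz
ph   <- generate_ois_stack(cfg)
rmap <- compute_response_map(ph$stack, stimulus_protocol())
rmap
#> <response_map> 64 x 64 px at 0.05 Hz; dR/R range [1.06e-06, 0.00105]
threshold_curve(rmap, thresholds = c(2.5, 5, 7.5) * 1e-4)
#>   threshold pixel_count
#> 1   0.00025         229
#> 2   0.0005          109
#> 3   0.00075          42
```

The peak recovered ΔR/R (~1.05×10⁻³) is the configured 10⁻³ plus noise;
109 pixels exceed half the peak, matching the analytic Gaussian-blob area
$\pi\cdot 2\sigma^2\ln 2 \approx 109$ px for σ = 5 px.

```r
## --- behavior: simulate a cohort, score learning
logs <- simulate_cohort(n_wt = 6, n_ko = 9, seed = 7)
tab  <- build_success_table(logs)
bs   <- block_rates(tab)

rm_anova_block_by_distance(bs, "WT", "whisker")
#>   genotype class   effect    F df1 df2          p n_mice n_distances
#> 1 WT       whisker block  58.9   1  15 0.00000144      6           3
rm_anova_block_by_distance(bs, "KO", "whisker")
#>   genotype class   effect     F df1 df2     p n_mice n_distances
#> 1 KO       whisker block  0.469   1  24 0.500      9           3
compare_improvement(bs, "whisker")
#>   class       t df          p mean_wt mean_ko mean_diff
#> 1 whisker  6.96 13 0.00000985    28.2   -2.10      30.3
```

The simulated WT cohort improves strongly at whisker-only distances
(block $F(1,15)=58.9$) while the KO cohort — whose agents carry no
whisker-distance learning — does not ($F(1,24)=0.47$, $p=0.50$); the
between-genotype difference in whisker improvement is ~30 percentage
points ($p\approx10^{-5}$). Note the df pattern: 6 mice × 3 whisker
distances give the block effect 15 error df, 9 mice give 24.
`plot_block_rates(bs)` draws the percent-success-vs-distance summary
figure for both blocks and genotypes.

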