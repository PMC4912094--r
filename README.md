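# helixkink

Kink angles in protein alpha-helices, with statistical confidence
intervals and conservation classification across homologous helices.

Kinks — sites where a helix axis changes direction — are common in
transmembrane helices and long soluble helices, and many are functionally
important (the conserved kinks of GPCR transmembrane helices 6 and 7 are
the classic example). Most kink-detection tools report an angle with no
error estimate, so it is impossible to say whether two homologous helices
are *significantly* differently kinked. `helixkink` is for structural
bioinformaticians who want to (1) measure per-site kink angles from
coordinates, (2) attach a calibrated 95% confidence interval to each
angle, and (3) classify kink conservation across pairs and families of
aligned homologous helices.

## The method

**Angle measurement.** A cylinder is fitted to every 6-residue segment of
a helix (m = 24 backbone atoms N, CA, C, O) by minimising, over axis
position and direction,

```
r = sqrt( (1/m) * sum_i (d_i - dbar)^2 )
```

where `d_i` is the distance of atom *i* from the axis and `dbar` their
mean. The kink angle at site *s* is the angle between the axes of the two
disjoint flanking segments (residues `s-5..s` and `s+1..s+6`, both
oriented N→C), assigned to the final residue of the first segment; hence
only helices of ≥ 12 residues can be analysed.

**Confidence intervals.** The fit qualities of the two flanking cylinders
predict the error of the angle:

```
epsilon = a * ln(r_n + r_c - c) + b        (degrees)
```

with shipped coefficients a = 6.349, b = 13.15, c = 0.2937. The 95%
interval is `theta ± epsilon`. `calibrate_error_model()` re-derives the
coefficients by a Monte-Carlo simulation: both fitted cylinders of a known
kink are randomly rotated about their midpoints, the angle deviation
`alpha = theta - true_angle` and the degraded `r_n + r_c` are recorded,
samples are binned by `r_n + r_c`, and the 95th percentile of |alpha| per
bin is log-fitted.

**Conservation classes.** At the most disrupted site of a pair (the
largest angle in either helix, partner matched within ±4 alignment
columns) or of a family (highest-mean column after 3-column max
smoothing, ≥ 5 angles), helices are classified as Conserved Straight,
Conserved Kinked, Not Conserved, or Other, using the 20° kink threshold
and the confidence intervals (pairs: `|Δθ| > ε1 + ε2`; families: angle
standard deviation vs mean error).

Everything is testable offline: `generate_ideal_helix()` /
`generate_kinked_helix()` build parametric helices with known geometry,
and `generate_family_fixture()` writes whole aligned-family fixtures.

## Worked example

```r
library(helixkink)

helix   <- generate_kinked_helix(20, kink_angle = 35, kink_position = 10,
                                 noise_sd = 0.15, seed = 42)
profile <- measure_angles(helix)   # default: shipped error model
profile
#> # A tibble: 9 × 7
#>   helix_id site_index auth_res theta_deg   r_n   r_c epsilon_deg
#>   <chr>         <int> <chr>        <dbl> <dbl> <dbl>       <dbl>
#> 1 kinked            5 6             4.36 0.324 0.325        6.58
#> 2 kinked            6 7             8.68 0.343 0.368        7.60
#> 3 kinked            7 8            19.5  0.320 0.432        8.19
#> 4 kinked            8 9            29.2  0.295 0.388        7.17
#> 5 kinked            9 10           30.2  0.304 0.391        7.34
#> 6 kinked           10 11           32.4  0.306 0.318        6.12
#> 7 kinked           11 12           32.9  0.325 0.312        6.35
#> 8 kinked           12 13           28.0  0.368 0.288        6.71
#> 9 kinked           13 14           14.1  0.432 0.273        7.51
```

The 35° kink built at residue 10 is measured as 32.9° ± 6.4° (the 0.15 Å
coordinate noise both perturbs the angle and, through poorer cylinder
fits `r_n + r_c`, widens the interval). `theta_deg` is the kink angle in
degrees at each site, `r_n`/`r_c` the flanking fit qualities in Ångström,
and `epsilon_deg` the half-width of the 95% confidence interval.
`autoplot(profile)` draws the profile with its confidence band.

Comparing two homologous helices at their most disrupted site:

```r
classify_pair(theta_max = 35.2, theta_min = 28.1, eps1 = 5.4, eps2 = 5.0)
#> [1] "ConservedKinked"     # both kinked; 7.1 < 10.4, not significant
```

From the shell, the same pipeline is available as subcommands:

```sh
helixkink synth --n 20 --kink-angle 30 --kink-pos 10 --seed 7 \
    --out helix.pdb --annot helices.tsv
helixkink measure --structure helix.pdb --helices helices.tsv --out angles.tsv
helixkink calibrate --n-samples 2000 --seed 1 --out model.json
```

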