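# dropcount

Enumeration of viable probiotic bacteria by three technologies — droplet
digital PCR (ddPCR) with a viability-dye treatment arm, serial-dilution
plate counting, and live/dead-gated flow cytometry — and the statistics
used to decide whether the methods agree: per-batch coefficients of
variation, Pearson correlation, regression against the identity line,
and Bland–Altman relative-difference analysis with 95% limits of
agreement.

It is written for quality and method-development scientists in the
probiotic/fermentation space who need to compare a rapid molecular count
against the plate-count gold standard across many production batches,
and for anyone who wants a tested, simulable reference implementation of
digital-PCR Poisson quantification.

## The models in brief

**ddPCR.** Template partitions randomly over ~20,000 droplets, so with a
positive-droplet fraction p̂ the mean occupancy is λ̂ = −ln(1 − p̂)
copies/droplet and the reaction holds λ̂/V_d copies/µL (V_d = droplet
volume, default 8.5e-4 µL). The dilution chain (fold dilution × 10⁴ µL
of primary suspension per gram of powder under 1:10 w/v rehydration)
converts to counts per gram. Wilson score intervals on p̂ are mapped
through the same transform; replicate wells are pooled droplet-wise
before the transform ("merged wells"). Viability-dye (PEMAX) treated
reactions count viable cells (`PCR.live`), untreated count all cells
(`PCR.total`).

**Plate counts.** Only plates with 25–250 colonies (inclusive) are used;
countable plates pool as Σcolonies / Σ(volume × dilution), scaled to
CFU/g.

**Flow cytometry.** Gated live/dead/total events per analyzed volume,
scaled through the dilution chain; the total gate is exactly live + dead.

**Agreement.** On the linear (never log) scale: per-batch replicate CVs
averaged per method; Pearson r and OLS of method 2 on method 1 for
per-batch means; Bland–Altman on relative differences
d = (x − y)/((x + y)/2) × 100 with limits of agreement mean(d) ± 1.96 sd(d).

A measurement-process simulator (`simulate_study()`) generates
50-batch, six-strain studies with the replicate structure (17 plates,
triplicate wells and flow replicates) and method-specific noise regimes
(plate ≫ flow > ddPCR) so the full pipeline is testable end to end.

## Worked example

Simulate a default 50-batch study, quantify all three technologies and
compare them:

```r
library(dropcount)

cfg <- pipeline_config(seed = 42)
res <- run_study(cfg)

dplyr::filter(res$report$cv_summary, stratum == "All")
#> # A tibble: 6 × 5
#>   stratum method     n_batches mean_cv_pct sd_cv_pct
#>   <chr>   <chr>          <int>       <dbl>     <dbl>
#> 1 All     Plate             50       18.3      3.93
#> 2 All     PCR.total         50        1.22     0.675
#> 3 All     PCR.live          50        1.30     0.721
#> 4 All     Flow.total        50        2.36     1.29
#> 5 All     Flow.live         50        2.66     1.41
#> 6 All     Flow.dead         50        2.78     1.22
```

Plate counting is by far the least consistent method (mean per-batch CV
~18%), flow cytometry sits near its ~3% replicate noise, and viable
ddPCR is the tightest (~1.3%): the variability ordering a method
comparison of these technologies shows.

```r
ag <- tidy(res$report$agreement)
dplyr::filter(ag, method_x == "Plate", method_y %in% c("PCR.live", "Flow.live")) |>
  dplyr::select(method_x, method_y, pearson_r, slope,
                mean_rel_diff_pct, loa_low_pct, loa_high_pct)
#> # A tibble: 2 × 7
#>   method_x method_y  pearson_r slope mean_rel_diff_pct loa_low_pct loa_high_pct
#>   <chr>    <chr>         <dbl> <dbl>             <dbl>       <dbl>        <dbl>
#> 1 Plate    PCR.live      0.997 1.04              -2.27      -12.8          8.28
#> 2 Plate    Flow.live     0.997 0.993              2.33       -8.19        12.9
```

Plate counts read ~2% *below* viable ddPCR on average (negative mean
relative difference): a fraction of dead-cell template survives the
viability treatment and inflates `PCR.live`. Single-well quantification
is just as direct:

```r
quantify_well(5000, 10000)$copies_per_ul_reaction
#> [1] 815.47   # lambda = ln 2 over the 8.5e-4 uL droplet
```

Figures mirroring the standard study graphics are one call each:
`plot_method_boxplot()`, `plot_method_scatter()` (with the y = x
reference) and `plot_bland_altman()`; `run_compare(..., out_dir = ...)`
writes them alongside TSV/JSON reports.

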