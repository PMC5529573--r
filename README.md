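# maxenvelope

Tools for analysing marine planktonic 16S/18S OTU tables along environmental
gradients, built for oceanographic amplicon surveys in which community
composition is compared across regions, seasons and depths. The package
covers the table-level bookkeeping (multiple rarefaction, prevalence and
shared-OTU summaries, taxon aggregation), phylogenetic diversity (Faith's PD,
weighted and unweighted UniFrac), Mantel comparisons of community and
environmental distance matrices, a mixed-layer-depth turbulence proxy with
turbulence-by-nutrient scenario classification, and — at its core —
**maximum-abundance envelope species distribution models**. A seeded
synthetic-community generator with known per-taxon response curves provides
ground truth for every stage.

## The maximum-abundance envelope model

A taxon's realised abundance at a station reflects many unmeasured factors;
its *potential* abundance along a single gradient is better described by the
upper envelope of the abundance cloud. For each gradient x (temperature,
salinity or depth) the procedure is:

1. **Categorise** the n observations into k = max(3, ⌈n/20⌉) equal-frequency
   categories, contiguous in sorted x — no category holds more than 20
   observations and there are at least 3.
2. **Envelope**: within each category, take the 95th percentile q of the
   taxon's abundance, the category median x̃, and the category size m.
3. **Fit** a GLM with log link and Poisson likelihood,
   log E[q] = β₀ + β₁x + … + β_d x^d, weighting each category by m.
4. **Select the degree** d ≤ 3: a higher degree is admitted only if it lowers
   the AIC *and* raises the proportion of deviance explained
   (1 − D_resid/D_null) by more than one percentage point; among admitted
   models the one explaining the most deviance wins, and degree 0 is reported
   when nothing beats the intercept-only model.
5. **Classify the shape** on a dense grid: flat, monotone_up, monotone_down,
   unimodal (one interior maximum), or other (≥ 2 maxima — the degree-limited
   signature of bimodality).

## Worked example

```r
library(maxenvelope)
library(dplyr)

sim <- simulate_community(gradient_design(n_samples = 120, seed = 1), n_otus = 60)
#> <synthetic_community> 60 OTUs x 120 samples; 4 focal response curves

kept <- filter_min_depth(sim$counts, 800)
reps <- rarefy_replicates(kept, 800, n_replicates = 10, seed = 1)
mean_counts <- count_table(round(Reduce(`+`, lapply(reps, as_count_matrix)) / 10))

suite <- run_envelope_suite(mean_counts, sim$metadata, variables = "temperature",
                            binning = binning_config(max_per_bin = 15))
tidy(suite) |> filter(taxon %in% names(sim$truth)[1:5]) |> select(-status, -n_peaks)
#> # A tibble: 5 × 8
#>   taxon     variable degree deviance_explained   aic shape peak_x peak_abundance
#>   <chr>     <chr>     <int>              <dbl> <dbl> <chr>  <dbl>          <dbl>
#> 1 syn_up    tempera…      1              0.941 1441. mono…   33.9           479.
#> 2 sar11_do… tempera…      3              0.809 1958. mono…   22.4           393.
#> 3 bathy_mid tempera…      3              0.882  979. other   27.4           103.
#> 4 proch_bi… tempera…      3              0.502 3942. other   22.4           961.
#> 5 cosmo_fl… tempera…      3              0.199 1537. other   33.9           115.
```

The monotone riser `syn_up` is recovered as a degree-1 climb peaking at the
warm end of the gradient (fitted envelope 479 reads at 33.9 °C); the
decliner `sar11_down` keeps its falling shape; the niche taxon `bathy_mid`
peaks mid-gradient near its true 28 °C optimum; and the bimodal taxon is
flagged `other`, the expected label when a cubic has to approximate two
peaks. `autoplot(suite, variable = "temperature")` draws the envelope points
and fitted curves.

Diversity, Mantel and the turbulence proxy chain the same way:

```r
pd <- diversity_over_replicates(reps, sim$tree, "pd")     # per-sample Faith's PD
uw <- diversity_over_replicates(reps, sim$tree, "uw_unifrac")
env <- env_distance(sim$metadata, c("temperature", "salinity", "nitrate"))
mantel_test(uw, env, n_perm = 999, seed = 1)
#> Mantel test (pearson): r = 0.0093, p = 0.374 (999 permutations, n = 120)

cast <- generate_profile(data.frame(depth = c(0, 84, 86, 200),
                                    temperature = c(25, 25, 22.5, 21.5),
                                    salinity = c(39.5, 39.5, 40.2, 40.2)))
mixed_layer_depth(cast)   # density criterion +0.125 kg/m3 vs the 10 m level
#> [1] 84.19318
```

A mixed layer of 84 m marks a deeply mixed, turbulent column;
`scenario_classify()` crosses that turbulence axis with a nutrient axis into
the four regime quadrants (North_Spring, North_Fall, South_Spring,
South_Fall). `run_pipeline(pipeline_config(...))` executes all stages in
order and writes TSV/JSON artifacts plus a manifest; reruns with the same
config and seed are byte-identical.

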