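# cropsuit

Mechanistic crop-suitability modelling for gridded monthly climate and
soil pH, with calibration, thresholding, multi-GCM ensembling and a
country/occurrence validation framework — plus a seeded synthetic-world
generator so the entire pipeline runs and is tested without any external
download.

## Who it is for

Researchers and analysts doing agro-ecological niche / climate-impact
assessments: where can a crop complete its growth cycle under current and
projected climate, how should a niche model be calibrated against
yield-derived references, and how should the resulting maps be validated
against occurrence points and national harvested-area statistics.

## The model

For each grid cell the engine scores all 12 candidate growing windows
(one per start month, December wraps to January; window length
`round_half_up((gmin + gmax)/60)` months). A window's score combines

- **temperature**: the minimum over window months of a trapezoidal
  response `f(T_m; tmin, topmin, topmax, tmax)`, forced to 0 for any
  month whose kill-test temperature (monthly minimum if available, else
  the mean) falls below `ktmp + 4` degC;
- **rainfall**: a trapezoidal response of the window's precipitation
  total, `f(sum P_m; rmin, ropmin, ropmax, rmax)`;

multiplied together (configurable to `min`). The best window's score,
multiplied by the soil-pH trapezoid `f(pH; phmin, phopmin, phopmax,
phmax)`, is the cell's suitability index in [0, 1] — a measure of
climatic feasibility, not a yield prediction.

Binary suitable/unsuitable layers use the threshold that equalizes
sensitivity and specificity (min |Se − Sp|) against a reference built by
marking cells below the 25th percentile of positive yields as unsuitable.
Crops that under-predict are calibrated by decrementing rainfall minima
in 10 mm steps, then (if still below the 0.7 match target) searching
kill-temperature and niche offsets in ±5 degC — see the methods vignette
(`vignettes/cropsuit-methods.Rmd`), including an honest analysis of which
degraded parameters this procedure can and cannot recover.

## Worked example

```r
library(cropsuit)

w   <- make_world(world_spec(xmin = 0, xmax = 25, ymin = -40, ymax = 40,
                             res = 1, seed = 42))
reg <- load_registry()
p   <- get_crop(reg, "maize")

suit <- map_suitability(w$stack, w$ph, p, crop_code = "maize", period = "curr")
#> geo_grid 80 x 25, values in [0, 1], 0 missing

yld <- make_yield_grid(make_truth(w, p), noise_sd = 0.1, seed = 7)
ref <- reference_from_yield(yld)
th  <- equalize_se_sp(as.vector(suit$values), as.vector(ref$labels))
#> threshold 0.4002: Se 0.986, Sp 0.985, |Se-Sp| 0.0004 (864 candidates)
bin <- binarize(suit, th$threshold)
percent_suitable_area(bin)
#> 48.5   (area-weighted percent of land suitable)

archive_name("Cereals", "maize", "suit", "s370", "gfdl")
#> "Cereals_maize_suit_s370_gfdl.tif"
attr(enumerate_runs(reg), "counts")$future_per_crop
#> 30    (3 scenarios x 10 GCMs per crop)

pts <- sample_occurrences(suit, 500, seed = 8)
fao <- make_harvest_table(bin, w$mosaic, seed = 9)
round(evaluate_crop(bin, pts, w$mosaic, fao, seed = 11), 3)
#>      gbif_detection   faostat_detection faostat_correlation
#>               0.895               1.000               0.752
#>  faostat_exceedance mapspam_correlation  mapspam_exceedance
#>               1.000                  NA                  NA
```

Reading the numbers: the Se=Sp threshold (0.40) balances true-positive
and true-negative rates against the yield-derived reference almost
exactly; 48.5% of the (area-weighted) land is classed suitable; 89.5% of
occurrence points fall in suitable cells; every "producing" country has
more than one grid cell of suitable area (detection 1.0); harvested and
suitable areas correlate positively (r = 0.75); and the modelled suitable
area exceeds the harvested area in every country, as a fundamental niche
should. MAPSPAM-style metrics are `NA` here because no such reference
table was supplied.

## Command line

```sh
Rscript -e 'cropsuit::cropsuit_cli()' synth --config cfg.json --seed 5 --outdir out
Rscript -e 'cropsuit::cropsuit_cli()' run --config cfg.json --outdir out
Rscript -e 'cropsuit::cropsuit_cli()' calibrate --config cfg.json --outdir out
```

Subcommands: `synth`, `run`, `calibrate`, `validate`, `ensemble`,
`manifest`; JSON config; layers are exchanged as plain-text ESRI ASCII
rasters named by the archive convention
`<class>_<crop>_<suit|suit_cl>_<period>[_<model>].<ext>`.
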