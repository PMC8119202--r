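# metaboflux

Quantitative analysis of plate-based cellular-metabolism assays, built for
studies of metabolic reprogramming in cells such as the retinal pigment
epithelium (RPE): extracellular flux (Seahorse-type) stress tests,
[U-13C]-glucose stable-isotope tracer analysis, mitochondrial morphometry
and the replicate/statistics conventions that connect plate wells to
biological conclusions. Every analysis module is paired with a seeded
synthetic-data generator, so the whole pipeline is testable against known
ground truth without instrument exports.

## What it computes

**Extracellular flux.** From per-well OCR/ECAR time series and an injection
schedule, the standard stress-test decomposition (rates per µg protein):

- mitochondrial stress test: nonmitochondrial respiration,
  basal = OCR<sub>pre-oligomycin</sub> − nonmito, proton leak,
  ATP production = basal − leak,
  maximal = max OCR<sub>FCCP</sub> − nonmito,
  spare capacity = 100 × maximal/basal, OCR/ECAR;
- glycolysis stress test: nonglycolytic acidification, glycolysis,
  glycolytic capacity, reserve = capacity − glycolysis;
- glycolytic rate assay: PER = ECAR × buffer constants,
  glycoPER = PER − ccf × OCR, basal and compensatory glycolysis,
  mitoOCR/glycoPER, %PER from glycolysis;
- acute-injection responses (e.g. LPS): per-well post/pre ratio, technical
  wells averaged per experiment, treated/control fold change.

**Isotope tracing.** Natural-abundance correction of mass-isotopolog
spectra by binomial-kernel deconvolution (nonnegative least squares),
labeled/unlabeled pool abundances, and the surrogate activity ratios
citrate M+2 / pyruvate M+3 (pyruvate dehydrogenase, PDH) and
citrate M+3 / pyruvate M+3 (pyruvate carboxylase, PC). A forward
atom-mapped glycolysis/TCA simulator (`simulate_mids()`) with a tunable
PDH:PC split, unlabeled anaplerotic dilution and TCA cycling provides
ground-truth MIDs, cross-checked against a molecule-level Monte-Carlo
oracle.

**Morphometry.** Shoelace areas (mean of repeated tracings), Feret
diameters and a reproducible three-class morphology call
(fragmented / short tubular / long tubular) from the elongation statistic
e = diameter / (2√(area/π)), plus per-field counts and densities.

**Statistics.** Technical→biological replicate aggregation, unpaired
two-tailed t tests, one-way ANOVA with Dunnett comparisons against control,
ΔΔCt relative expression, media-difference consumption/production, ATP/ADP
ratios and fold changes, assembled into tidy CSV reports with a JSON
manifest of every convention used.

## Worked example

Simulate an IL-33 knockdown mitochondrial stress test (3 biological repeats
× 2 technical wells per group), extract parameters, and test maximal
respiration:

```r
library(metaboflux)

plate <- simulate_plate(xf_preset("il33_kd", seed = 11))
tab <- xf_analyze_plate(plate, "mito")
maxresp <- tab[tab$parameter == "maximal_respiration", ]
bio <- aggregate_technical(data.frame(experiment_id = maxresp$experiment,
                                      condition = maxresp$group,
                                      value = maxresp$value))
bio
#>   experiment_id condition     value n_wells
#> 1            E1   il33_kd  8.585275       2
#> 2            E2   il33_kd  9.093891       2
#> 3            E3   il33_kd  8.607868       2
#> 4            E1  scramble 15.741016       2
#> 5            E2  scramble 14.720305       2
#> 6            E3  scramble 14.254053       2

compare_groups(split(bio$value, bio$condition)[c("scramble", "il33_kd")],
               "two_group", control = "scramble")
#>           comparison   effect       test statistic df      p_value
#> 1 il33_kd - scramble -6.14278 t (pooled)   -13.087  4 0.0001968211
```

The knockdown group loses about 6 pmol O2/min/µg of FCCP-stimulated maximal
respiration relative to scrambled control (p ≈ 2 × 10⁻⁴), the direction the
scenario encodes.

Isotope tracing with a 60:20 PDH:PC flux split:

```r
mids <- simulate_mids(label_network_config(phi_pdh = 0.6, phi_pc = 0.2))
mids$citrate
#> <mid_profile> citrate
#>    M+0    M+1    M+2    M+3    M+4    M+5    M+6
#> 0.3698 0.0047 0.4778 0.0441 0.0545 0.0453 0.0038
pdh_surrogate(mids$citrate, mids$pyruvate)   # 0.530905
pc_surrogate(mids$citrate, mids$pyruvate)    # 0.04898816
```

The M+2-dominated citrate pattern reflects PDH-routed M+3 pyruvate losing
one carbon as CO2; the surrogate ratios rank the two entry fluxes.

A thin command-line wrapper covers the same pipelines
(`inst/cli/metaboflux.R`; see `?metaboflux_cli`):

```sh
Rscript inst/cli/metaboflux.R xf simulate --preset lps_acute --seed 7 \
    --out plate.csv --config-out assay.yaml
Rscript inst/cli/metaboflux.R xf analyze --plate plate.csv --config assay.yaml \
    --test acute --event lps --treated lps_acute --control control --out fold.csv
```

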