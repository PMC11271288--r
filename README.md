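# arcmegan

Isoprene emission modelling for Arctic and boreal ecosystems: the
MEGANv2.1 temperature activity factor plus updated response functions for
the two dominant high-latitude isoprene emitters — sedges (*Carex*,
*Eriophorum*) and willows (*Salix*) — whose temperature sensitivity and
emission capacity acclimate to the recent temperature history. The package
is aimed at ecosystem modellers and flux scientists who want to fit
leaf-chamber temperature-ramp experiments, confront site-level flux models
with eddy-covariance observations, and quantify emission trends, all with
seeded synthetic-data generators for testing every stage without external
downloads.

## The model

MEGAN computes isoprene flux as an emission factor modulated by
dimensionless activity factors. The default short-term temperature
response is

    gamma_T = Eopt * CT2 * exp(CT1/R * (1/Topt - 1/T))
              / (CT2 - CT1 * (1 - exp(CT2/R * (1/Topt - 1/T))))

with activation energy CT1 = 95 kJ mol⁻¹, deactivation energy
CT2 = 230 kJ mol⁻¹, and acclimating optimum

    Topt = 313 + 0.6 (T240 - 297.15)
    Eopt = 2 exp(0.05 (T24 - 297.15)) exp(0.05 (T240 - 297.15))

where T24 and T240 are the mean air temperatures of the previous 24 and
240 hours (K). This response has a Q10 near 3 — far below the Q10 > 8
observed for tundra ecosystems.

The sedge update replaces the curve by a pure Arrhenius exponential whose
activation energy and capacity acclimate in opposite directions to the
10-day mean:

    gamma_T_sg = exp(0.12 (T240 - 288.15)) * exp(C_sg/R (1/303.15 - 1/T))
    C_sg       = 95 + 9.5 exp(0.53 (288.15 - T240))

Cold-acclimated sedges are extremely temperature sensitive (C_sg above
200 kJ mol⁻¹ below ~283 K) but have low emission capacity; after warm
spells the activation energy relaxes to the default 95 kJ mol⁻¹ while the
capacity grows. The willow update keeps the default curve shape but lets
the capacity track the previous-day mean:

    Eopt_willow = 7.9 exp(0.22 (T24 - 297.15))

Site flux is a mixture over plant functional types i with cover
fractions CF_i:

    F = sum_i  eps*_i CF_i * (LAI/LAI_max) * gamma_T_i * gamma_others

where eps*_i is the canopy-level emission factor (leaf EF × 1.5) and
gamma_others collects the canopy factor (0.3) and the remaining activity
factors. `fit_cover_fractions()` estimates the CF_i by bounded least
squares against half-hourly eddy-covariance flux, using daytime
observations (PPFD > 300 µmol m⁻² s⁻¹).

## Worked example

Generate a synthetic 60-day half-hourly site record with true cover
fractions (sedge 0.25, shrub 0.10) and 10% additive noise, then recover
the fractions:

```r
library(arcmegan)

sim <- gen_site(synthetic_config(seed = 42), n_days = 60)
fit <- fit_cover_fractions(sim$series, sim$pfts)
print(fit)
#> Site flux fit (cover fractions; n = 1612, PPFD > 300):
#>   sedge      0.2494
#>   shrub      0.1010
#>   R2 = 0.988, RMSE = 0.009 nmol/m2/s
```

The fitted fractions land within 0.002 of the truth; R² is the squared
Pearson correlation between modelled and observed half-hourly flux, RMSE
is in flux units (nmol m⁻² s⁻¹). Chamber experiments work the same way:

```r
exps <- gen_chamber(synthetic_config(seed = 42, n_experiments = 6))
fit_arrhenius(exps[[1]])
#> Arrhenius fit (synthetic_sedge_01): Ea = 93.0 kJ/mol,
#>   EF30 = 19.72 nmol/m2/s, R2 = 0.999 (n = 5)
```

`Ea` is the activation energy (slope of ln emission against
`(1/303.15 - 1/T)/R`) and `EF30` the emission factor at 30 °C; this
experiment drew a warm 10-day mean (292.3 K), hence an Ea near the
default 95 kJ mol⁻¹. The contrast between regimes in one line each:

```r
q10(function(T) gamma_t_default(T))        # 2.977  (default response)
q10(function(T) gamma_t_sedge(T, 283.15))  # 20.2   (cold-acclimated sedge)
```

A command-line wrapper over the same functions ships in `inst/exec/`
(subcommands `synth`, `fit-chamber`, `fit-site`, `simulate`, `trend`).

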