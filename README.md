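# eagledemog

Demographic analysis of territorial raptor populations under
anthropogenic mortality, built around the golden eagle (*Aquila
chrysaetos*) life cycle: juvenile year, three subadult years, then
adulthood as either a territory-holding breeder or a non-breeding
floater.

In a saturated territorial population the breeding census is buffered:
floaters fill territory vacancies as they occur, so heavy mortality can
leave occupancy surveys looking stable while consuming the entire
reproductive surplus. This package quantifies that hidden cost from
radio-telemetry and nest-survey data:

* **Known-fate survival** — product-binomial maximum likelihood over
  3-month seasonal intervals with staggered entry, relocation-based
  risk sets, censoring, a four-model candidate set {S(.), S(t),
  S(sex), S(sex×t)} and AICc ranking; annual survival
  \(S_{ann}=\prod_i S_i\) with delta-method variance and logit-scale
  confidence intervals. Analytic censoring of turbine-related or all
  human-related deaths gives "what-if" survival scenarios.
* **Fecundity and sex ratio** — fledglings per pair, brood size, nest
  success; likelihood-ratio G-tests of 1:1 parity; the female-fledgling
  rate \(f = \text{rate} \times p_{female}\) with product delta-method SE.
* **Potential growth rate** — a five-stage, single-sex,
  post-breeding-pulse matrix model whose dominant root solves
  \(\lambda^4(\lambda-S_b)=S_b f S_j S_s^3\), with sensitivities by
  implicit differentiation and SE by the independent-rates delta
  method.
* **Moffat's equilibrium** — the floater-to-breeder ratio
  \(F{:}B = (R-V)/(1-S_f)\) with recruitment \(R=S_b f S_j S_s^3\) and
  vacancy rate \(V=1-S_b\), cross-validated by an individual-based
  simulation.
* **Demographic cost** — the replacement chain
  \(P_0\sum_k r^k\) of breeding pairs whose output is consumed by one
  fatality of a given age, where \(P_0=1/(f_2\varphi(a))\) and
  \(r=2(1-S_b)/(f_2 S_j S_s^3 S_b)\), scaled to annual mortality tolls.
* **A stochastic individual-based simulator** of the whole system
  (territories, floater buffer, monthly mortality with causes, radio
  tagging, detection and transmitter censoring) that generates the
  package's input formats and serves as an oracle for the analytic
  models.

## Worked example

```r
library(eagledemog)
report <- run_pipeline(pipeline_config())
print(report)
```

```
Demographic analysis report
  mean reproduction: 0.639 fledglings/pair
  growth rates:
    all_deaths         baseline_60mo        lambda = 0.997 (SE 0.025)
    all_deaths         early_breeding_48mo  lambda = 1.004 (SE 0.026)
    turbine_censored   baseline_60mo        lambda = 1.040 (SE 0.024)
    turbine_censored   early_breeding_48mo  lambda = 1.051 (SE 0.025)
    human_censored     baseline_60mo        lambda = 1.072 (SE 0.023)
    human_censored     early_breeding_48mo  lambda = 1.086 (SE 0.025)
  F:B at equilibrium:
    all_deaths         -0.03 (infeasible)
    turbine_censored   0.46
    human_censored     1.52
  cost: 3.844 pairs per fatality after 6 rounds
```

Reading this: with every observed death counted, the potential growth
rate sits at replacement (λ ≈ 1.0) — a population generating no floater
surplus, where any further drop in vital rates opens unfillable
territory vacancies. Censoring blade-strike deaths lifts λ to 1.040 and
supports roughly one floater per two breeding females (F:B ≈ 0.5);
censoring all known human-caused deaths gives λ = 1.072 and F:B ≈ 1.5.
The cost model says each blade-strike fatality (mean age 40 months)
consumes the entire annual output of ≈3.8–3.9 territorial pairs, so a
toll of 55–65 deaths per year occupies the production of 216–256 pairs:

```r
replacement_chain(canonical_vital_rates("turbine_censored"))
#> Demographic cost of one fatality at 40 months [turbine_censored]
#>   initial pairs 2.256; per-round ratio r = 0.4144
#>   cumulative series: 2.256, 3.190, 3.578, 3.738, 3.805, 3.832, 3.844
#>   limit 3.852 pairs per fatality
footprint(reference_pairs_per_fatality(), 55)
#> 55 deaths/yr -> 216 pairs (216.2); resident fraction 1.00 -> 216 pairs
```

To generate a synthetic study and estimate everything from data rather
than the canonical published rates:

```r
sim <- simulate_population(sim_config(seed = 1))
report <- run_pipeline(
  pipeline_config(use_published_rates = FALSE, seed = 1),
  histories = sim$histories, surveys = sim$surveys)
```

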