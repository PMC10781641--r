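# divdrivers

Decoupling the abiotic and biotic drivers of speciation and extinction in
clades with rich fossil records.

For a time-calibrated phylogeny that retains its extinct tips, speciation
and extinction histories can be estimated separately rather than only
through their difference. `divdrivers` partitions such a tree by tip
ecology (marine / freshwater / terrestrial, plus a combined non-marine
partition), estimates speciation rate λ(t), extinction rate μ(t) and net
diversification r(t) = λ(t) − μ(t) on a fixed time grid, and tests each
candidate driver — palaeotemperature T(t), eustatic sea level S(t), and the
partition's own lineage diversity N(t) (diversity dependence) — against
each rate curve with two complementary statistics:

* **Detrended cross-correlation (DCCA).** Both series are integrated into
  profiles, linearly detrended in overlapping boxes of one analysis scale,
  and correlated through the detrended residuals:
  ρ = F²xy / (Fx·Fy) ∈ [−1, 1]. This guards against spurious correlation
  between non-stationary, autocorrelated series. The coefficient is
  computed against every realization of a posterior-style ensemble of rate
  curves; a driver–rate pair is *reported* when |mean ρ| > 0.1, with
  percentile intervals and a Wilcoxon signed-rank p-value alongside.
* **Shannon transfer entropy (TE).** Directional information flow
  TE(X→Y) = Σ p(y⁺, yᵏ, xˡ) log₂ [p(y⁺|yᵏ, xˡ) / p(y⁺|yᵏ)] in bits, on
  equal-width-discretized series whose state count is selected by
  HMM–AIC; significance by a Markov block bootstrap of the source, with an
  effective-TE (null-mean-subtracted) correction. A result is *retained*
  when p < 0.001 and TE > 0.1 bits.

A synthetic-data module generates environment-coupled birth–death trees
with extinct tips, habitat evolution and posterior-style rate ensembles so
the whole pipeline is testable end to end with known ground truth, and a
Baum–Ragan MRP module encodes source-tree clades into weighted TNT/NEXUS
matrices for supertree work.

## Worked example

Simulate a study in which speciation (but not extinction) is coupled to a
temperature anomaly, then ask the pipeline to find the driver:

```r
library(divdrivers)

study <- simulate_study(seed = 7)      # ~200 Myr clade, 2000-6000 tips
report <- run_pipeline(study$tree, study$habitat,
                       study$drivers["temperature"],
                       partitions = "non-marine", dcca_scale = 40,
                       te = te_config(state_range = 2:8, n_repeats = 5,
                                      n_bootstrap = 1000),
                       noise = ensemble_noise(200, 0.2, 5), seed = 42)
report$correlations[, c("driver", "rate_type", "mean", "reported")]
```

```
       driver  rate_type        mean reported
1 temperature speciation  0.22671371     TRUE
2 temperature extinction -0.02663258    FALSE
3 temperature        net  0.21104695     TRUE
4         LTT speciation -0.01956382    FALSE
5         LTT extinction  0.02561371    FALSE
6         LTT        net -0.03049091    FALSE
```

```r
report$te[, c("driver", "rate_type", "te", "p", "retained")]
```

```
       driver  rate_type         te           p retained
1 temperature speciation 0.48717900 0.000999001     TRUE
2 temperature extinction 0.11060419 0.291708292    FALSE
3 temperature        net 0.42740897 0.000999001     TRUE
4         LTT speciation 0.11536812 0.888111888    FALSE
5         LTT extinction 0.15259684 0.299700300    FALSE
6         LTT        net 0.06604704 0.884115884    FALSE
```

The generating truth is recovered: the temperature–speciation pair is
reported (mean ρ = 0.23 > 0.1) with significant information transfer
(TE = 0.49 bits, bootstrap p ≈ 0.001), while temperature–extinction is
neither reported nor retained, and the biotic (LTT) driver — which drives
nothing in this simulation — is silent. Net diversification inherits the
speciation signal. Because single-draw DCCA coefficients of *null* pairs fluctuate
with a noise floor of roughly √(scale/N), conclusions about flags should
be drawn over several independent draws (see the methods vignette); the
verification script below does exactly that.

`run_sensitivity()` repeats the analysis over alternative trees and
tabulates cross-tree sign consistency; `mrp_encode()` + `write_tnt()` /
`write_nexus()` cover the supertree encoding side.

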