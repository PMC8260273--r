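# vconn — virtual connectome completion with whole-brain network models

Connectomic datasets describe each subject's brain twice: a **structural
connectome** (SC), the weighted matrix of anatomical coupling between
parcellated regions, and a **functional connectome** (FC), the Pearson
correlation matrix of regional resting-state BOLD signals. Real cohorts
are full of gaps — subjects with an SC but no FC, or the reverse. `vconn`
fills those gaps by *model-based completion*: it embeds the available
connectome in a whole-brain network model, runs or inverts the model, and
returns the missing counterpart as a "virtual" connectome, together with
the validation metrics needed to judge the result. It is aimed at
researchers building analysis or machine-learning pipelines on connectome
matrices who need principled surrogates for missing data, or arbitrarily
many stochastic replicas for data augmentation.

Two model families are implemented end to end:

* **Linear (SLM)** — coupled Ornstein–Uhlenbeck processes
  `dx = (-I + G W) x dt + σ dW` on the SC graph `W` (spectrally
  normalized so the critical coupling is 1). The stationary covariance is
  closed-form, `C = -(σ²/2)(-I + G W)⁻¹`; its correlation normalization
  is the virtual FC, and the inversion `W* = -C⁻¹/G_ref` (diagonal
  zeroed, `G_ref = 0.83`) is the virtual SC. No simulation required.
* **Nonlinear (MFM)** — reduced Wong–Wang neural masses,
  `dSᵢ/dt = -Sᵢ/τ_S + (1-Sᵢ) γ Rᵢ + σηᵢ` with
  `xᵢ = ωJ_N Sᵢ + J_N G Σⱼ C_ij Sⱼ + I₀`, integrated with a compiled
  Euler–Maruyama core and passed through a Balloon–Windkessel
  hemodynamic stage to emulate BOLD at TR 2 s. The working point
  `(G*, τ*)` is located without any empirical target by jointly
  maximizing three criteria on short simulations (spatial heterogeneity
  of activation, FC clustering, dFC clustering). FC→SC inversion grows an
  *effective connectivity*: starting from a random symmetric matrix,
  `SC⁽ᵏ⁺¹⁾ = SC⁽ᵏ⁾ + λ(FC_target − FC⁽ᵏ⁾)` until the simulated FC
  correlates with the target at `CC_target = 0.7`.

Chaining both directions produces **bivirtual duals** (SC → virtual FC →
bivirtual SC, or FC → virtual SC → bivirtual FC); repeating the
stochastic forward completion under many seeds produces **virtual
cohorts**. A synthetic-connectome generator (stochastic block model with
log-normal weights, jittered multi-subject cohorts) makes every pipeline
testable without any neuroimaging data, and a metrics module provides the
comparison toolkit: upper-triangle fit correlation, weighted clustering,
PageRank centrality, signed-weight Louvain communities, relative mutual
information with permutation chance levels, Δ-coefficients for
improvement over trivial completion and by personalization, IQR-restricted
correlations, and inter-subject distance correspondence.

## Worked example

```r
library(vconn)

# a 20-region, 2-module synthetic ground truth (largest eigenvalue 1)
sc <- generate_sc(synth_spec(n_regions = 20, n_modules = 2, seed = 5))

# --- linear completion: closed form, no simulation -----------------------
fc_slm <- linear_sc_to_fc(sc)                   # virtual FC at G_ref = 0.83
sc_slm <- linear_fc_to_sc(fc_slm)               # and back

# --- nonlinear completion at a fixed working point -----------------------
p <- mfm_params(G = 1.5, tau_s_ms = 25)         # sigma 0.03, T = 4e5 ms
fc_mfm <- nonlinear_sc_to_fc(sc, c(1.5, 25), p, seed = 100)
fit_correlation(sc, fc_mfm)                     # SC-FC coupling:   0.426
fit_correlation(fc_mfm,                         # seed-to-seed FC
  nonlinear_sc_to_fc(sc, c(1.5, 25), p, seed = 101))  #  reproducibility: 0.836

# --- invert an FC back into an effective SC ------------------------------
res <- nonlinear_fc_to_sc(fc_mfm, ec_params(mfm = p, seed = 7), truth_sc = sc)
res$trace
#> <ec_trace> 57 iterations, stop = target_reached, final cc(FC*, FC_target) = 0.707
fit_correlation(res$sc, sc)                     # recovered vs true SC: 0.58
```

The trace shows the defining behavior of the effective-connectivity
iteration: the fit to the target FC climbs from ≈0 (a random initial
matrix is uncorrelated with the target) until it crosses the 0.7 stop
threshold, while the hidden correlation to the true SC rises in parallel
(here 0.11 → 0.58 — far above the ≤0.08 node-permutation null, so the
recovered matrix reproduces genuine structure, not just scale).

## Command-line use

A thin wrapper over the same functions lives at `inst/cli/vconn`:

```sh
vconn synth-sc --n 20 --seed 1 -o sc.tsv
vconn sc2fc --method slm sc.tsv -o fc.tsv
vconn fc2sc --method mfm --g 1.5 --tau 25 --seed 1 fc.tsv -o sc_mfm.tsv --trace trace.tsv
vconn metrics sc.tsv sc_mfm.tsv -o report.json
```

All outputs are TSV matrices with a label header plus a `.meta.json`
sidecar recording kind, provenance, method, parameters and seed.

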