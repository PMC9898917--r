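# thagg

Thermodynamic and aggregation fingerprinting of immunoglobulin light
chains (IgLCs), as an R analysis pipeline.

Free monoclonal light chains overproduced in plasma-cell disorders range
from harmlessly soluble to amyloid-forming, and no single biophysical
parameter separates the two.  A standardized multiparametric
characterisation — thermal and chemical stability, aggregation onset and
its concentration dependence, turbidity behaviour, amyloid kinetics,
protease digestibility — yields a per-sample *fingerprint* that can be
compared across patients and related to clinical covariates.  This
package implements the full data-analysis layer of such a workflow, for
biophysicists and computational biologists working with nanoDSF/DLS
temperature scans, ThT plate-reader kinetics and proteomics fragment
maps.

## What it computes

**Protease cleavage analysis** — an 8-position (P4–P4′) log-odds PSSM
per protease from substrate windows, with pseudocount *q* = 5:

    p(a,j) = (n(a,j) + q) / (N + 20q),   s(a,j) = ln p(a,j)/b(a)

Sequences are scored by sliding window sums, taking the per-position
maximum over the cathepsin-B- and cathepsin-D-style matrices; scores
convert to cleavage probabilities through the logistic
σ(s) = e^s/(1+e^s) (σ(1.5) ≈ 81.7%).  Observed peptide-fragment termini
define a proximal region (start−2…start+1 ∪ end−1…end+2), and a
one-tailed Mann–Whitney U test — exact by complete enumeration for small
groups, tie- and continuity-corrected normal approximation otherwise —
asks whether cleavage scores at fragment edges exceed the rest of the
sequence.

**Thermal-scan analysis** — Tm as the maximum of the first derivative of
the smoothed 350/330 nm fluorescence ratio; aggregation onset Tagg from
the DLS cumulant radius by the 0.5% divergence rule (linear baseline
extrapolation vs. sigmoidal fit); d Tm/d log c and d Tagg/d log c in °C
per decade; and the turbidity maximum of the capillary Bence-Jones test
with its reversibility flag.

**Unfolding thermodynamics** — a global two-state
Gibbs–Helmholtz + linear-extrapolation fit across the urea grid and both
emission wavelengths,

    ΔG(T,c) = ΔHm (1 − T/Tm) + ΔCp (T − Tm − T ln(T/Tm)) − m·c,

yielding ΔG(37 °C) with a 100-fold capillary-bootstrap confidence
interval; the m-value can be fixed (conventionally 7.1 kJ mol⁻¹ M⁻¹) or
fitted.

**Aggregation kinetics** — per-trace fits of
Y = y_i + m_i t + (y_f + m_f t)/(1 + e^{−(t−t50)/k}) giving the halftime
t50, plus fold increase and ThT-corrected aggregated fraction.

**Fingerprint statistics** — reversible categorical encodings
(small/medium/large → 0.33/0.50/0.66; 0/<50/>50 → 0/1/2), mean
imputation and standardisation, pairwise-complete Pearson/Spearman
correlation matrices, and elastic-net regression with 4-fold
cross-validated grid search that reports the CV score alongside the
(optimistic) in-sample correlation.

**Synthetic data** — seeded generators for substrate windows with
planted specificity motifs, proteome-like parent sequences and their
digestion fragments, two-state melt curves, DLS radius traces with a
planted onset, turbidity scans and ThT traces — each an exact forward
model of the corresponding analysis, with ground truth attached.

## Worked example

```r
library(thagg)

## cleavage: PSSMs from synthetic substrate windows, edge enrichment
cfg   <- synth_config(seed = 1)
ds    <- gen_cleavage_dataset(cfg, seq_len = 400, n_fragments = 25)
pssms <- lapply(split(ds$windows, ds$windows$protease), build_pssm)
prof  <- score_sequence(ds$sequence, unname(pssms))
edge_enrichment_test(prof, proximal_mask(ds$fragments, nchar(ds$sequence)))
#> One-tailed Mann-Whitney edge-enrichment test (proximal greater)
#>   U = 22374.0 (n_edge = 130, n_nonedge = 263, normal)
#>   p = 3.147e-07 (< 0.05)

## thermodynamics: global two-state fit + capillary bootstrap
truth  <- default_stability_truth()          # dG(37 degC) = 20.25 kJ/mol
curves <- gen_melt_curves(truth, T_grid = seq(20, 70, by = 2.5),
                          n_capillaries = 3, seed = 2)
bootstrap_ci(curves, n_boot = 100, seed = 3, fix_m = 7.1)
#> dG(37 degC) = 20.26 kJ/mol, 95% bootstrap CI [20.25, 20.27] (100/100 replicates)

## kinetics: sigmoidal ThT fit
fit_sigmoid(gen_tht_trace(seed = 4))
#> Sigmoidal ThT fit: t50 = 11.974 h, k = 1.021 h, fold increase = 15.54
```

The edge test recovers the planted cathepsin-like specificity from the
fragment map (p ≈ 3×10⁻⁷); the global fit recovers the planted folding
free energy of 20.25 kJ/mol within its bootstrap interval; the kinetics
fit recovers the planted 12 h halftime to 0.2%.

## Package layout

- `R/synthgen.R` — seeded generators and ground truth
- `R/cleavage.R` — PSSMs, profiles, proximal regions, edge test
- `R/thermostab.R` — Tm, Tagg, concentration slopes, turbidity
- `R/foldfit.R` — two-state model, global fit, capillary bootstrap
- `R/aggkin.R` — ThT sigmoid fits, fold increase, aggregated fraction
- `R/fingerprint.R` — encodings, correlations, elastic-net CV
- `R/io.R` — FASTA/TSV/CSV/JSON interchange
- `vignettes/thagg-methods.Rmd` — models, assumptions, design choices
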