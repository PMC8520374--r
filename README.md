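# ctpdeconv

Tracer-kinetic deconvolution of dynamic CT perfusion (CTP) with a
weighted-adaptive total-variation (WA-TV) prior.

In acute stroke imaging, a contrast bolus is tracked through the brain over
a short dynamic CT series (20 frames at 2 s here). Every voxel's
time–dose curve is the causal convolution of the arterial input function
B(t) with the voxel's flow-scaled residue function G(t) = CBF·R(t):

    c = A g,     A[i, j] = dt · B[i − j]   (lower-triangular Toeplitz)

Recovering G from noisy curves is an ill-posed inverse problem. This
package solves it with iterative shrinkage-thresholding (ISTA) under an
edge-adaptive TV prior

    min_G  ½ Σ_v ‖A g_v − c_v‖² + λ Σ_v δ·atan( s(v) / δ ),
    s(v) = Σ_t ‖∇G_t(v)‖,

whose majorization–minimization surrogate is a weighted TV with the
Perona–Malik weight w(v) = 1/(1 + (s(v)/δ)²): the prior relaxes at strong
intensity edges and keeps full strength in flat, noisy regions. Truncated
SVD, Tikhonov and plain spatial TV baselines are included, along with:

* a digital brain perfusion phantom (gamma-variate AIF, core-infarct and
  penumbra lesions with relative severities, smooth tissue texture,
  analytic ground truth, seeded Gaussian noise);
* perfusion maps — CBF (residue peak), CBV (curve-area ratio), MTT
  (central-volume theorem), TTP (curve argmax) — and mirror-symmetric
  relative maps (rCBF, rCBV, rMTT, rTTP, percent of contralateral);
* a paired PSNR/MSE/MAE evaluation harness for solver comparison;
* a CLI (`phantom`, `deconvolve`, `maps`, `evaluate`) over NIfTI, CSV and
  YAML/JSON files.

Who it is for: researchers prototyping or benchmarking CTP deconvolution
algorithms who need a fully synthetic, ground-truthed test bed; it is not
a clinical tool.

## Worked example

```r
library(ctpdeconv)

spec <- phantom_spec()                 # 64x64x1, 20 frames x 2 s, CIA + PI lesions
ph   <- build_phantom(spec)
sys  <- build_conv_matrix(ph$aif, spec$time$dt)
noisy <- add_noise(ph$series, sigma = 2, seed = 7)

fit <- ctp_solve(noisy, sys, solver_config("wa_tv"))
fit
#> <ctp_solve_result> method = wa_tv, 138 iterations, converged = TRUE
#>   final objective 171242 (fidelity 159740, prior 11502.1)

maps <- perfusion_maps(fit$G_hat, conv_forward(sys, fit$G_hat), ph$aif, spec$time)
rel  <- compute_relative_maps(maps, ph$masks$brain, "left")
round(sapply(c("rcbf","rcbv","rmtt","rttp"),
             function(p) mean(rel[[p]][ph$masks$pi], na.rm = TRUE)), 1)
#>  rcbf  rcbv  rmtt  rttp
#>  26.0  33.2 128.0 148.9
```

These are the penumbra's relative perfusion values (percent of
contralateral) estimated from one noisy realization: markedly reduced flow
and volume with prolonged transit and peak times. On the *noiseless*
series with the exact (pseudo-inverse) solver the same means reproduce the
phantom's severity parameters — rCBF 18.4, rCBV 33.6, rMTT 183.1,
rTTP 151.2 — where rCBV is the central-volume-consistent severity realized
by the phantom (rCBF·rMTT/100; see the methods vignette). Under noise, the
WA-TV estimate scores higher PSNR and lower MSE/MAE than plain TV and
default Tikhonov on all four parameter maps; with 20 paired noise seeds at
2 HU the mean PSNR margin of WA-TV over plain TV is about +0.9 dB.

The full model, phantom design, parameter defaults and their rationale are
documented in `vignettes/ctp-watv-methods.Rmd`.

## Command line

```sh
Rscript inst/cli/ctpdeconv.R phantom    --config run.yaml --out out/phantom --seed 1
Rscript inst/cli/ctpdeconv.R deconvolve --config run.yaml --out out/deconv  --seed 1
Rscript inst/cli/ctpdeconv.R maps       --config run.yaml --out out/maps
Rscript inst/cli/ctpdeconv.R evaluate   --config run.yaml --out out/eval   --seed 1
```

Exit codes: 0 success, 2 validation error, 3 solver failure. Each
subcommand prints a manifest and writes a `run_log.json` with the config
hash and seed.

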