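# tautcnv

Copy number variants (CNVs) leave their signature in sequencing depth: the
readcount of a genomic window is, in expectation, proportional to the local
copy number. In practice the per-window log2 ratio of a sample against a
matched normal is so noisy that segmentation algorithms call many false
CNVs and miss narrow ones. `tautcnv` is an R package for read-depth CNV
detection that attacks this at the source: it denoises the log2-ratio
signal with the **taut string**, the exact linear-time solver of 1-D
total-variation (TV) regression, before segmenting and calling.

For a noisy signal `r = f + ε` with `f` piecewise constant and sparse and
`ε ~ N(0, σ_N²)` i.i.d., the denoised estimate solves

    f̂ = argmin_f  ½ Σᵢ (rᵢ − fᵢ)²  +  ϑ Σᵢ |fᵢ₊₁ − fᵢ|

via the shortest string through a tube of radius ϑ around the running-sum
curve, pinned at both ends. The tube radius starts at `0.5·λ` with
`λ = c·√n·σ̂` and `σ̂ = 1.48/√2 · median|rᵢ₊₁ − rᵢ|`, and is locally
squeezed by a factor γ wherever the residuals violate a multiresolution
bound, which is what recovers narrow CNVs without letting noise through.
Segmentation is circular binary segmentation (CBS) with a permutation split
test; segments are called amplification/deletion/neutral by a strict ±thr
rule on the denoised log2 ratio and merged into maximal same-call regions.
Moving-average and Haar-wavelet-shrinkage denoisers are included as
baselines, together with a benchmark simulator and segment-overlap
evaluation metrics (sensitivity, FDR, specificity at ≥80% benchmark
overlap, and exact breakpoint accuracy).

The audience is anyone building or benchmarking read-depth CNV pipelines
from windowed readcount tracks (bedGraph / BED4+GC at a fixed window
width, 100 bp by default).

## Worked example

```r
library(tautcnv)

# one benchmark signal: 34,000 windows, 16 CNVs of log2 amplitude +/-1,
# heavy Gaussian noise (sigma_N = 0.42)
rep <- cnv_benchmark_suite(seed = 1, n_signals = 2)[[2]]
res <- detect_cnvs(rep$signal, method = "tautstring",
                   cbs = cbs_params(seed = 1002), thr = 0.2)
subset(res$segments, call != "neutral")[1:3, ]
```

```
  start_idx end_idx mean_value     call
2      1420    1440 -0.4830406 deletion
4      2924    3010 -0.7951273 deletion
6      4449    4717 -0.8725722 deletion
```

Each row is a detected CNV region: 1-based window indices, the mean
denoised log2 ratio (a value near −1 means one copy lost against a diploid
normal), and the call. Evaluated against the simulated truth at the ≥80%
overlap rule:

```r
segment_overlap_eval(res$segments, rep$truth, min_frac = 0.8)
```

```
<eval_result> TP 14  FP 0  FN 2 | sensitivity 0.875  FDR 0.000  specificity 0.998  breakpoints 0.188
```

14 of the 16 simulated CNVs are recovered with no false region at a noise
level where the signal is barely visible by eye. A linear smoother on the
same signal shows why edge-preserving denoising matters — the moving
average smears breakpoints and lets hundreds of noise bumps through the
±0.2 calling rule:

```r
ma <- detect_cnvs(rep$signal, method = "ma", cbs = cbs_params(seed = 1002))
segment_overlap_eval(ma$segments, rep$truth)
```

```
<eval_result> TP 15  FP 322  FN 1 | sensitivity 0.938  FDR 0.955  specificity 0.869  breakpoints 0.062
```

A file-based pipeline (`run_pipeline()`: filter → GC-correct → log2 ratio →
denoise → segment → call, with per-stage logging) and a thin command-line
front end (`inst/cli/tautcnv.R` with subcommands `simulate`, `denoise`,
`segment`, `evaluate`, `pipeline`) wrap the same functions for shell use.

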