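# svdfusion

Noise-aware, color-preserving fusion of paired medical images: a grayscale
anatomical MRI and a color-mapped functional PET are combined into a single
RGB image that carries the MRI's structural detail on the brightness plane
while keeping the PET's metabolic color map untouched. The package is
aimed at image-analysis researchers who need a fully reproducible,
dependency-light fusion pipeline with a complete quality-metric suite and
synthetic test data, so every stage can be exercised offline.

## Method

All fusion happens on the luminance plane of a YUV representation; the
PET chrominance planes (U, V) pass through bit-exactly.

Each luminance plane is split by the singular value decomposition
I = U Σ Vᵀ into a low-frequency structural component L = U Σ_k Vᵀ (the
best rank-k approximation) and a high-frequency residual H = I − L.

* **Low-frequency fusion** is energy-adaptive:
  α = E_MRI / (E_MRI + E_PET) with E = Σ L(i,j)², and
  L_f = α·L_MRI + (1 − α)·L_PET.
* **High-frequency fusion** is feature-gated:
  H_f = ((μ_MRI + μ_PET)/2) · H_PET, where μ is the mean activation of a
  VGG19-style convolutional feature extractor applied to the min–max
  rescaled HF map. The gate is a single scalar; the extractor (random,
  fine-tuned, or stub weights) plugs in through one interface.
* **Reconstruction**: Y_f = L_f + H_f, reattached to the PET's U/V planes
  and converted back to RGB.

Around this core the package provides modality-specific noise simulation
(Gaussian for MRI, Poisson photon noise for PET), the hybrid denoising
chain (bilateral filtering; non-local means + guided filtering), YUV and
YCbCr conversion, the metric suite EN / SD / AG / MSE / PSNR / SSIM / CC
plus a bounded perceptual distance with a three-reference protocol, a
seeded phantom-pair generator, ablation modes (`svd_only`, `vgg_only`,
`rgb_svd_vgg`, truncated ranks, YCbCr), a self-supervised fine-tuning
loop for the extractor, and a CLI.

## Worked example

```r
library(svdfusion)

pair <- make_phantom_pair(seed = 7, size = 256)   # synthetic MRI/PET pair
cfg  <- fusion_config(backbone = "small", seed = 7)
res  <- fuse_pair(pair$mri, pair$pet, cfg)
print(res)
#> fused_result: 256x256, mode=svd_vgg, color_space=yuv, k=full
#>   LF weights: alpha=0.6369 beta=0.3631
#>   HF gate: mu_mri=0.0111 mu_pet=0.0175 gate=0.0143

evaluate(res, reference = pair$gt_proxy)
#>      en     sd      ag    mse  psnr   ssim     cc
#> 1 4.492 0.2866 0.01885 0.0027 25.69 0.9821 0.9859
```

`alpha` is the MRI share of the low-frequency blend (here the MRI carries
~64% of the structural energy); the gate is the scalar applied to the PET
detail map. The metric row reads: entropy 4.49 bits and SD 0.29 describe
the fused image's information and contrast; SSIM 0.982 and CC 0.986
against the pair's synthetic ground-truth proxy confirm the fused
luminance tracks the blended reference closely. The chrominance planes of
`res$fused_rgb` equal the PET's exactly — `res$u` and `res$v` are the
untouched input planes.

The same pipeline is available from the shell:

```sh
SCRIPT=$(Rscript -e 'cat(system.file("cli", "svdfuse.R", package = "svdfusion"))')
Rscript $SCRIPT phantom --seed 7 --size 256 --out-dir demo/
Rscript $SCRIPT fuse --mri demo/mri.png --pet demo/pet.png \
        --out demo/fused.png --report demo/report.csv
```

Commands: `fuse`, `denoise`, `simulate-noise`, `metrics`, `ablate-rank`,
`phantom`, `train-extractor`; all accept `--config cfg.yaml` and
`--seed`, and every CLI run reproduces the corresponding API call
bit-exactly.

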