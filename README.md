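# occlumap

Digital restoration of molar occlusal surfaces from triangle meshes, as
an R package. A prepared (drilled) tooth is turned into a calibrated
8-bit depth map, the preparation area is extracted as a binary mask, and
the missing relief is filled by inverting a generative model of healthy
occlusal surfaces — then merged, evaluated in millimetres, and
back-projected to a mesh. The intended users are researchers in dental
CAD and biomedical image analysis who want every stage of such a
pipeline as a testable, scriptable unit.

## The method

For a clean occlusal depth map `x_cln` and a binary mask `M` (1 =
retained, 0 = preparation area), the corrupted observation is the
Hadamard product `x_cor = x_cln ⊙ M`. Reconstruction seeks the latent
matrix `w` (n_res × 512, with n_res = 2(log₂ w − 1)) of a fixed
generator `G` that minimizes

```
L_B =   λ_pixel   ‖M ⊙ (x − G(w))‖² / N
      + λ_percept ‖F(M ⊙ x) − F(M ⊙ G(w))‖² / N_F
      + λ_w       ‖w − μ_w‖² / N_w
      + λ_colin   mean(1 − cos(w_i, w_j))
      + λ_pixel,B ‖x − G(w)‖²_{M_B} / N_B
```

with the published operating point λ_w = −3.2, λ_colin = 8.6e−4,
λ_pixel = 6.7e−4, λ_percept = 9.2e3, λ_pixel,B = 4.0e−4. The last term
is evaluated only on `M_B`, the one-pixel ring of retained pixels around
the removed region: it pins the generated fill to the preparation edge.
The merge `x_merge = x_cor + |M − 1| ⊙ G(w*)` then satisfies the edge
boundary condition exactly. Optimization is Adam (α = 0.05) over
restarts, keeping the restart with minimal final loss.

Upstream of the inversion the package implements pose normalization
(minimum-volume oriented bounding box derotation, then iterated
PCA-plane leveling of the occlusal surface), calibrated top-surface
rasterization with in-plane canonicalization, and the normal/height
heuristic that extracts the preparation mask. A parametric
synthetic-molar generator (superellipse footprint, four cusps, central
fossa, four carve-able preparation types of rising removed area)
provides exact ground truth for every stage. The full-scale generative
model is a style-based GAN trained offline; the package ships a
contract-complete linear PCA stand-in and treats the GAN as a pluggable
adapter.

## Worked example

```r
library(occlumap)
cfg <- projectionConfig()

## a small population of synthetic molars and their canonical depth maps
teeth <- generateToothDataset(21, toothShapeParams(), seed = 7)
maps  <- lapply(seq_along(teeth), function(i)
    projectTooth(teeth[[i]], cfg, seed = i))
G <- fitLinearGenerator(mirrorAugment(maps[-1]), rank = 16)

## carve an interior inlay preparation into the held-out tooth
spec   <- preparationSpec("a", teeth[[1]]@metadata$params)
carved <- carvePreparation(teeth[[1]], spec)
zT <- spec$floorZ + (cfg@zNorm - max(vertices(carved$mesh)[, 3])) + 0.2
mx <- extractPreparationMask(carved$mesh, cfg, maskThresholds(0.3, zT),
                             seed = 1)
mx$mask
#> BinaryMask [extracted]: 128x128, removed (0) pixels: 1745

## reconstruct the removed area by latent inversion and merge
xCor <- corrupt(pixels(mx$map), mx$mask)
res  <- optimizeLatent(xCor, mx$mask, mx$boundary, G,
                       opt = optimizerConfig(nR = 300, nRestarts = 2,
                                             seed = 1))
res
#> ReconstructionResult: 2 restart(s), chosen #2
#>   final loss 36301.6 after 300 steps; diminishing returns at step 300

## compare against the uncorrupted tooth
xTrue <- projectTooth(teeth[[1]], cfg, seed = 1)
rmseVsTruth(res@xMerge, pixels(xTrue), calibration(cfg))
#> [1] 0.0408232
```

The mask removes 1745 pixels (about 29 % of the visible occlusal area,
the size class of a small interior inlay). The reported value is the
full-image RMSE between the merged reconstruction and the uncorrupted
ground truth: 0.041 mm, about 2.3 intensity units at the 4.5 mm depth
window — a restoration error well below clinically visible scale on
this synthetic testbed. "Diminishing returns at step 300" equal to the
trace length means the loss was still improving when the step budget
ran out.

`runPipeline(pipelineConfig(...))` chains all stages end to end and
writes PNG/CSV/JSON artifacts with provenance sidecars;
`inst/scripts/occlumap` is a thin command-line wrapper
(`occlumap run --seed 42 --out results/`).

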