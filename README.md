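# colporeg

Unsupervised, colour-preserving registration of acetowhitening colposcopy
time sequences.

During a dynamic colposcopy exam, a sequence of RGB frames (typically 17) is
captured at fixed intervals after dilute acetic acid is applied to the
cervix. The transient epithelial whitening is the diagnostic signal — but
patient and camera motion shifts the cervix between frames, and no
registration ground truth exists with which to train a supervised aligner.
`colporeg` implements an unsupervised deep-learning registrar for such
sequences, together with the mask-overlap evaluation protocol used to score
it and a synthetic acetowhitening phantom benchmark with exact ground truth.

## Method

Each colour channel gets its own registration branch: a convolutional
encoder–decoder g<sub>θ</sub> (channel widths
`[16, 32, 32, 32, 32, 32, 32, 16]`, 3×3 kernels, Leaky-ReLU) that maps a
(fixed, moving) channel pair to a dense displacement field
u ∈ ℝ<sup>H×W×2</sup>, applied by a differentiable spatial-transform layer
(backward warp, bilinear, clamp-to-edge):

    m′(p) = m(p + u(p)),   L = Σ_c [ sim(f_c, m′_c) + λ ‖∇u_c‖² ]

Training is per sequence and fully unsupervised: random fixed/moving frame
pairs (batch size 1) from the photometrically augmented pool of one
sequence, three-branch loss aggregated and backpropagated (Adam). Spatial
augmentations are deliberately excluded. At inference, frames 2..n are each
registered to frame 1, per channel. Quality is scored as the Dice/IoU of
each frame's cervix mask against frame 1's, before vs. after registration.

The network, the warp layer, reverse-mode gradients and the optimizer are
implemented in the package itself (R + C++ kernels with BLAS); a
finite-difference test verifies the analytic gradients.

## Worked example

```r
library(colporeg)

# a 17-frame, 64x64 acetowhitening phantom with rigid misalignment
ph <- generate_sequence(phantom_config(seed = 1))
evaluate_sequence(ph$truth$masks)
#> eval_report: 17 frames; mean Dice 0.876, mean IoU 0.784

# train the three-branch registrar on this sequence (a few minutes on CPU)
run <- train_on_sequence(ph, desk_profile(seed = 101))
run
#> training_run (rgb): 14 epochs x 90 steps; mean total loss 0.0421 -> 0.0301

# register frames 2..17 to frame 1 and score the ground-truth masks
reg <- register_sequence(run, ph)
masks_reg <- c(list(ph$truth$masks[[1]]),
               lapply(2:17, function(t)
                 transport_mask(ph$truth$masks[[t]], reg$fields[[t]])))
evaluate_sequence(masks_reg)
#> eval_report: 17 frames; mean Dice 0.933, mean IoU 0.875

improvement(0.876, 0.933)
#> [1] 6.506849
```

The mean mask overlap rises from 0.876 to 0.933 — the registrar has undone
most of the injected rigid misalignment (translations up to 6 px, rotations
up to 4° at 64×64) using nothing but the frames themselves.

The same flow is available from the shell via the bundled CLI
(`inst/cli/colporeg`): `simulate`, `train`, `register`, `evaluate`, and
`run` for the whole pipeline from a YAML config; see
`vignettes/colporeg-methods.Rmd` for the model details and design
rationale.

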