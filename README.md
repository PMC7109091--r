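# mrcnn — multi-resolution convolutional networks for image-to-image inverse problems

Imaging science is full of problems where the forward direction is easy to
simulate and the inverse direction is what you actually need: recovering a
wavefront's phase from defocused intensity measurements, restoring clean
atomic-resolution frames from low-dose scanning transmission electron
microscopy (STEM) data, or inverting a differential operator applied to an
image. `mrcnn` implements a generic learned solver for this class of
problems, together with everything required to study it without any
external data: seeded synthetic forward models, a training loop, and
frequency-resolved evaluation metrics.

## The model

The core is a U-Net — an encoder of stride-2 convolution stages and a
mirrored decoder with skip connections — whose decoder stages emit
additional *coarse outputs*: the feature at side *n*/2<sup>k</sup> feeds
one extra 3×3 convolution producing a prediction at that resolution. Every
output is supervised against the matching level of an area-average pyramid
of the target, with loss

&nbsp;&nbsp;&nbsp;&nbsp;L = Σ<sub>k=0..B</sub> w<sub>k</sub> · mean |ŷ<sub>k</sub> − y<sub>k</sub>|,

so the low-frequency content of the solution is fitted at every scale
simultaneously instead of being left to emerge slowly through the full
resolution head alone. With B = 0 branches the model *is* the plain U-Net
baseline, built layer-identical under the same seed, which makes paired
convergence comparisons exact. A denoising variant prepends a fixed bank
of four low-pass filters (two box kernels, two broad Gaussians) to the
input, converting denoising into deblurring and making the trained model
robust to changing noise levels; an optional least-squares conditional-GAN
stage refines its predictions towards realistic structure.

The synthetic forward models cover Fresnel defocus propagation (unitary,
FFT-based), annular dark-field atomic-image synthesis (Gaussian peaks on a
canvas), a compound noise pipeline (Poisson → Gaussian → uniform →
clipping, all seeded), and the inverse-Laplacian toy task used to probe
convergence. Metrics are MAE, SNR in decibels, and Fourier ring
correlation (FRC).

## Worked example

```r
library(mrcnn)

# seeded synthetic inverse-Laplacian dataset: input = discrete Laplacian
# of a random texture, target = the texture
train_set <- sample_training_set("laplacian", n = 64, seed = 1, side = 64)
test_set  <- sample_training_set("laplacian", n = 16, seed = 2, side = 64)
train_set
#> <mrcnn_dataset> kind 'laplacian', 64 pair(s) of 64x64 images (seed 1)

spec <- mcnn_spec(depth = 4, n_branches = 3, base_width = 16, seed = 1)
net <- build_mcnn(spec)
net
#> <mcnn_net> plain cells, depth 4, 4 supervised output(s), 241,812 trainable parameters
build_unet(spec)   # identically seeded zero-branch baseline
#> <mcnn_net> plain cells, depth 4, 1 supervised output(s), 240,801 trainable parameters

fit <- train_network(net, train_set,
                     train_config(iterations = 150, learning_rate = 3e-3, seed = 1),
                     test_set = test_set)
glance(fit)
#> # A tibble: 1 × 5
#>   iterations final_train_loss final_test_mae best_test_mae parameters
#>        <int>            <dbl>          <dbl>         <dbl>      <dbl>
#> 1        150            0.304          0.108        0.0939     241812

item <- test_set$items[[1]]
pred <- predict(fit$network, item$input)
metric_report(item$target[, , 1], pred)
#> # A tibble: 1 × 3
#>      mae snr_db frc_mean
#>    <dbl>  <dbl>    <dbl>
#> 1 0.0966   13.3    0.745
```

After 150 iterations the network reconstructs held-out textures from
their Laplacians with a test MAE around 0.09–0.11 (intensities are
normalised to [0, 1]), an SNR of ~13 dB on the shown frame, and a mean
ring correlation of ~0.75 — low frequencies recover first, which is
exactly what the coarse supervision is for. `autoplot(fit)` draws the
loss/MAE history; `run_convergence_experiment()` runs the full paired
MCNN-vs-U-Net comparison and `autoplot()` of its result overlays the two
test-MAE curves.

A command-line front end (generate / train / predict / evaluate /
reproduce-fig1 subcommands) is installed at `inst/cli/mrcnn.R`.

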