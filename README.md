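# rvt — recurrent convolutional vision models with entropy-threshold decisions

Feedforward convolutional networks dominate models of primate vision, yet the
ventral stream is densely recurrent, and — unlike a feedforward model — a
primate can trade speed for accuracy, spending more time on harder images.
`rvt` is an R toolkit for studying that trade-off in recurrent convolutional
neural networks (rCNNs) with **lateral** (within-layer) connections. It is
aimed at computational neuroscientists and vision modellers who want to
exercise the full modelling pipeline — architecture accounting, anytime
decision rules, speed–accuracy analysis, reaction-time fitting, and
connectivity analysis — at desk scale, on synthetic data, without GPUs or
external datasets.

## The model family

The baseline feedforward network **B** stacks seven convolutional blocks
(stride-1, size-preserving convolutions; 2×2 stride-2 max pooling between
blocks) with a global-average-pool + dense softmax readout. A layer computes

    H_{t,n} = φ( W_n^b ∗ η(H_{t,n−1}) + b_n )

where `∗` is convolution, `η` optional max pooling and `φ` batch
normalisation followed by rectification. The recurrent network **BL** adds a
lateral convolution from the layer's own activations one time step earlier,

    H_{t,n} = φ( W_n^b ∗ η(H_{t,n−1}) + W_n^l ∗ H_{t−1,n} + b_n )

unrolled for T = 8 time steps with a category readout at every step (lateral
state at t = 0 is the zero stack, so t = 1 is exactly the feedforward
sweep). Because recurrence adds parameters, the package also builds the
parameter-matched feedforward controls **B-K** (larger kernels), **B-F**
(doubled feature maps), **B-D** (two convolutions per block), and the
graph-matched control **B-U** (BL unrolled with unique weights per time
step).

Decisions are made anytime-style: the network runs until the Shannon entropy
(in nats) of its **cumulative readout** — the running mean of the per-step
softmax outputs — falls to or below a threshold θ; the first crossing is the
network's *reaction time*, and sweeping θ traces a speed–accuracy trade-off
(SAT) against the cumulative floating-point cost. A companion pipeline fits
θ to human subject×image reaction-time matrices by double leave-one-out
cross-validation of a recurrent sigmoid readout
`y_t = σ(α y_{t−1} + w·p_t + b)` on PCA-projected activations, and a
lateral-weight analysis decomposes the learned K×K lateral kernels
(one *weight template* per ordered feature-map pair) into principal
components.

## Worked example

Architecture accounting at full scale is exact and instantaneous:

```r
library(rvt)
spec <- make_spec("BL")          # the published 7-block recurrent network
count_parameters(spec)
#> trainable parameters: 28,870,920 (28.9 million)
#>   bottom_up  8,980,256
#>   lateral    17,773,568
#>   biases     0
#>   batchnorm  68,096
#>   readout    2,049,000
count_parameters(build_bu(spec))$total / 1e6   # unrolled control, unique weights
#> [1] 212.71712
```

The breakdown shows why BL is interesting: recurrence recycles 28.9M
parameters over eight sweeps of computation, while the graph-matched
feedforward control needs 212.7M to do the same work. A desk-scale run of
the whole decision pipeline:

```r
task <- synth_task(n_classes = 10, image_size = 16, n_per_class = 50, seed = 101)
tiny <- make_spec("BL", list(n_blocks = 2, base_f = 8, input_size = c(16, 16, 3),
                             n_classes = 10, n_timesteps = 4))
fit <- rcnn_train(tiny, task, train_config(epochs = 14, batch_size = 20,
                                           learning_rate = 0.01,
                                           adam_epsilon = 1e-3, seed = 1,
                                           augment = FALSE))
fit
#> <rcnn_net> BL | 2 blocks | T = 4 | 4,610 trainable parameters
#>   trained 14 epochs | final train acc 0.735 | val acc 0.560

test <- synth_task(n_classes = 10, image_size = 16, n_per_class = 20, seed = 901)
seqs <- predict(fit, preprocess_batch(test$x, "eval", 16))
head(decide(seqs, decision_policy(entropy_threshold = 1.0)), 3)
#>   predicted_class reaction_time   entropy    cost
#> 1              10             4 1.1545717 3392768
#> 2               8             4 1.2236880 3392768
#> 3              10             2 0.9968303 1696384

curve <- sat_curve(seqs, test$y)
curve
#> <sat_curve> 802 thresholds (nats), accuracy 0.435-0.555, mean cost 8.48e+05-3.39e+06
```

Each row of `decide()` is one image: an easy image reaches the entropy
criterion after 2 of 4 time steps and costs half the floating-point
operations of a hard one. The SAT curve shows accuracy rising from the
single-sweep 0.435 to 0.555 as the threshold is tightened and mean cost
grows — the model spends computation only where it is needed.
`matched_cost_threshold(curve, cost)` picks the θ whose mean cost matches a
feedforward competitor, and `mcnemar_test()` compares the matched models.
See the methods vignette (`vignettes/recurrent-vision-models.Rmd`) for the
reaction-time fitting and lateral-component analyses.

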