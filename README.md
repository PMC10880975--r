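# dpcnet

Dynamic predictive coding networks in R: a hierarchical spatiotemporal
generative model of visual sequences in which a higher cortical level does
not predict pixels but *modulates the transition dynamics* of the level
below, so that higher levels come to represent sequences over longer
timescales. The package is for computational neuroscientists who want a
compact, fully inspectable implementation of this model family — its
inference and learning rules, and the classic experimental probes
(space-time receptive fields, timescale hierarchies, the flash-lag
illusion, cue-triggered activity recall, higher-order sequence structure)
— running entirely on generated stimuli.

## The model

Frames `I_t ∈ R^M` are generated from a sparse code `r_t ∈ R^N` through
spatial filters `U`; the code's dynamics are a mixture of `K` learned
transition matrices, with mixture weights produced from the higher-level
state `r_h ∈ R^{N_h}` by a small feedback network (a hypernetwork) `H_θ`:

    w = H_θ(r_h),   V = Σ_k w_k V_k
    r_t | r_{t-1}, r_h ~ N(ReLU(V r_{t-1}), σ_r² I)
    I_t | r_t          ~ N(U r_t, σ² I),      r_h ~ N(0, I)

Perception is per-step MAP inference by gradient descent on the
prediction-error loss

    L_t = ‖I_t − U r_t‖²/(2σ²) + ‖r_t − ReLU(V r̂_{t-1})‖²/(2σ_r²)
          + λ‖r_t‖₁ + λ_h‖r_h‖²,

with both levels corrected each step (filtering with a point-mass
posterior). Learning minimizes the same losses over a corpus at the MAP
latents. A Hebbian associative memory binds `[r_0; r_h]` for episodic
storage and cue-triggered recall, and a three-level extension gates
second-level transitions by a first-level prediction-error threshold,
letting the third level encode how dynamics themselves change (e.g.
bounce rules). The methods vignette
(`vignettes/dpcnet-methods.Rmd`) documents every modeling and numerical
choice.

## Quick start

```r
library(dpcnet)

## a small two-level network with known parameters
shape   <- dpc_shape(M = 16, N = 8, N_h = 2, K = 2, hidden = 4)
teacher <- dpc_params(shape, seed = 1)

## sample a 10-frame sequence from the generative model
g <- sample_generative(teacher, T_len = 10, sigma2 = 1e-4, sigma_r2 = 1e-4,
                       seed = 7)
round(g$w, 3)   # true mixing weights for this sequence
#> [1] 0.025 0.114

## filter it back: per-step MAP inference of both latent levels
hyper <- dpc_hyper(sigma2 = 0.1, sigma_r2 = 0.1, lambda = 0.001,
                   lambda_h = 1e-4)
opts  <- dpc_options(lr_r = 0.02, lr_rh = 0.05, max_iters = 1500,
                     tol = 1e-9, backtrack = FALSE)
traj <- filter_sequence(g$seq, teacher, hyper, opts)
round(traj$pred_err_l2, 3)   # image prediction error per step
#>  [1] 3.125 1.828 0.037 0.045 0.037 0.041 0.046 0.042 0.047 0.044
round(traj$w[, 10], 3)       # inferred mixing weights at the last step
#> [1] 0.037 0.143
```

The prediction errors are largest in the first two steps — the filter
needs two frames to identify a sequence's dynamics — and then collapse;
the inferred mixing weights recover the true ones.

Typical workflow for the full experiments: generate stimuli
(`make_moving_sprites()`, `make_bouncing_dataset()`,
`make_white_noise()`, `make_drifting_surrogate()`), train with
`train_two_level()`, then analyze with `compute_strf()`,
`response_autocorrelation()` / `fit_exponential_decay()`,
`crossval_decode()`, `flash_lag_experiment()` / `latency_sweep()`,
`run_recall_experiment()`, and the three-level functions
(`estimate_threshold()`, `pretrain_second_level()`,
`infer_three_level()`, `train_three_level()`). A command-line surface
(`run_cli()`; thin wrapper in `inst/scripts/dpcnet-cli.R`) exposes the
same pipelines as subcommands (`gen-data`, `train`, `infer`, `strf`,
`autocorr`, `flashlag`, `memory`, `train3`, `report`) driven by a
`key: value` config file and a seed.

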