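# msinfo

Multiscale stochastic information processing with nonlinear summation
and integration.

## What it is for

Biological and artificial systems — gene circuits, signalling cascades,
neural populations — encode an input signal into an output through
nonlinear operations spread across separated timescales. `msinfo`
implements a paradigmatic model of this situation: stochastic *units*
(input *I*, optional processing *P*, output *O*), each a group of
linearly coupled Ornstein–Uhlenbeck degrees of freedom with its own
timescale, wired feed-forward through saturating activations

$$
\tau_\mu \dot{\mathbf x}_\mu = -\hat A_\mu \mathbf x_\mu
 + \sum_\nu g_{\mu\nu}\,\boldsymbol\phi_{\mu\nu}(\mathbf x_\nu)
 + \sqrt{2\tau_\mu}\,\hat\sigma_\mu\boldsymbol\xi_\mu ,
$$

with two competing activation conventions:

* **nonlinear summation** — `tanh` each source channel, then combine:
  $\phi^i = \frac1{C_i}\sum_j A^{ij}\tanh(x_j-\theta_j)$;
* **nonlinear integration** — combine first, then `tanh`:
  $\phi^i = \tanh\big(\frac1{C_i}\sum_j A^{ij}(x_j-\theta_j)\big)$.

For slow inputs and either fast or slow processing, the stationary
joint density factorizes exactly into conditional Gaussians whose means
carry all the nonlinearity (in the fast regime through the
Gaussian-smoothed activation
$\mathcal F(x,v) = \mathbb E_{z\sim N(x,v)}[\tanh z]$). The package
provides these exact solutions, seed-reproducible exact samplers,
Langevin integrators for cross-validation, nonparametric estimators of
the input–output mutual information $I_{IO} = H_O - H_{O|I}$ (bits),
Sarle's bimodality coefficient, and ensemble drivers that average over
random interaction matrices. It is aimed at researchers studying
information transmission in multiscale stochastic networks.

## A worked example

```r
library(msinfo)

sys <- random_system(M_I = 20, M_P = 20, g_PI = 5, g_OP = 10,
                     scheme = "integration", regime = "fast_processing",
                     seed = 1)
fact  <- build_factorization(sys)
batch <- sample_fast_processing(sys, N = 5000, seed = 2,
                                factorization = fact)
mi_fast(batch, factorization = fact)
#> I(input; output) = 2.3481 bits  (H_O = 4.3952, cond. = 2.0471, knn, n = 5000)
sarle_b(batch$x_O[, 1])
#> Sarle b = 0.5306 (skewness -0.047, excess kurtosis -1.113, n = 5000)
```

The mutual information between the 20-dimensional input and the scalar
output is ≈ 2.35 bits for this realization of the random couplings: the
output entropy (4.40 bits) minus the closed-form conditional entropy of
the Gaussian output factor (2.05 bits). The bimodality coefficient well
above the Gaussian reference 1/3 (with clearly negative excess
kurtosis) says the output distribution is bimodal — the saturating
integration scheme has turned the Gaussian input into a switch-like
output. Ensemble-level statements use
`ensemble_mi()` / `run_sweep()`, which redraw the random matrices per
realization and report means, spreads and per-draw values;
`reproduce()` packages the main experiment designs (trajectory overlap,
coupling/heterogeneity sweeps, processing-size tradeoff, bimodality
grid) at a chosen scale. A thin command-line front end lives in
`inst/cli/msinfo.R`.

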