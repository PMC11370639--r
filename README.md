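# gpnet

Classification of diagnostic groups from plasma-protein expression with a
**graph propagational network (GPN)**: per-protein expression is propagated
globally over a weighted protein–protein interaction (PPI) network by a
closed-form Laplacian-regularized operator, mixed back with the raw
expression through a trainable combining ratio, and fed to a softmax
classifier trained with analytic gradients. The motivating application is
dementia-subtype diagnosis (MCI / AD / VD) from Olink-style NPX panels with
STRING interaction evidence, but every interface takes an arbitrary class
set and network.

## The model

For expression `X` (p proteins × n samples) and Laplacian `L = D − W` of the
PPI weight matrix `W`:

* interactive effect — `F = (I + μL)⁻¹X`, the minimizer of
  `‖F − X‖² + μ·tr(FᵀLF)`; the smoothness `μ ≥ 0` sets the propagation
  range (μ→0 local, μ→∞ component means);
* combined effect — `Z = θF + (1−θ)X`, `θ = logistic(α)`;
* diagnosis — `P = softmax(βᵀZ)`.

`(α, μ, β)` are trained jointly by full-batch ADAM on the ridge-regularized
cross-entropy `𝓛 + δ(α² + μ² + ‖β‖²)` using closed-form gradients (verified
against finite differences in the test suite). The smoothness grid member is
selected on a validation split when one is supplied. Alongside the model the
package ships network statistics, one-vs-rest AUROC/AUPRC evaluation, a
(μ, θ) parameter sweep, TSV/JSON readers and writers, a synthetic cohort
generator, and a small CLI (`inst/cli/gpn.R`).

## Worked example

```r
library(gpnet)

sn  <- simulate_ppi_network(seed = 7)        # 26-protein two-block network
sim <- simulate_expression(sn$network, seed = 8)  # 271 + 121 samples, 3 classes
L   <- graph_laplacian(sn$network)

fit <- gpn_train(sim$discovery$X, L, sim$discovery$Y, seed = 7,
                 X_val = sim$validation$X, Y_val = sim$validation$Y)
fit
#> graph propagational network
#>   proteins: 26, classes: MCI/AD/VD
#>   theta = 0.2587 (alpha = -1.0528), mu = 8.098, delta = 0.001
#>   final training loss 0.636884 after 2000 epochs

pred <- predict(fit, sim$validation$X, L)
metric_report(pred$P, sim$validation$Y)
#> macro AUROC 0.7207, macro AUPRC 0.5214
#>   MCI (n=85): AUROC 0.7549, AUPRC 0.8537
#>   AD (n=26): AUROC 0.7765, AUPRC 0.5242
#>   VD (n=10): AUROC 0.6306, AUPRC 0.1863
```

`theta` is the trained weight on the network-propagated features (0.26 here:
about a quarter of each feature comes from the interactive effect), `mu` the
selected propagation range, and the report gives one-vs-rest AUROC/AUPRC per
diagnosis plus macro averages over the validation cohort.

Network descriptives for the simulated biomarker subnetwork:

```r
network_stats(sn$network, sn$groups)
#> network: 26 nodes, 67 edges, density 20.62%
#>   intra-group: 38 edges, mean weight 0.33
#>   inter-group: 29 edges, mean weight 0.22
```

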