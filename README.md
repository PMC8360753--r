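# bnreg — Bayesian network-constrained gene selection

`bnreg` selects disease-associated genes from expression data by Bayesian
regression with a **network-constrained shrinkage prior**: the coefficient
prior is shaped by the normalized Laplacian of a gene-interaction network
(e.g. pathways extracted from a curated database), so that interacting genes
receive similar, jointly shrunk effects. It is aimed at analysts doing
biomarker discovery on sample-limited expression studies who have pathway
or interaction structure they want the selection to respect, and who want
credible intervals for the effects rather than a bare gene list.

## The model

With standardized expression $X$ ($n \times p$) and response $y$,

$$y \mid X,\beta,\sigma^2 \sim N_n(X\beta, \sigma^2 I), \qquad
\beta \mid \sigma^2,\tau^2,r \sim N_p\!\big(0,\tfrac{\sigma^2}{r}\Lambda^{-1}\big),
\qquad \Lambda = \mathrm{diag}(1/\tau_j^2) + L,$$

where $L$ is the network's normalized Laplacian and the local scales
$\tau_j^2$ carry exponential-type priors. Because

$$\beta'\Lambda\beta = \sum_j \frac{\beta_j^2}{\tau_j^2}
 + \sum_{u\sim v} w(u,v)\Big(\tfrac{\beta_u}{\sqrt{d_u}}-\tfrac{\beta_v}{\sqrt{d_v}}\Big)^2,$$

the prior combines $\ell_1$-type sparsity with smoothness of degree-scaled
coefficients over network edges — the Bayesian analogue of the
network-constrained penalty
$\|y-X\beta\|^2 + r\lambda\|\beta\|_1 + r\,\beta'L\beta$. Special cases:
$L = 0$ gives the Bayesian lasso form, $L = I$ the Bayesian elastic net
form. All full conditionals are closed form (conjugate priors throughout,
with a generalized-inverse-Gaussian conditional for the $\tau_j^2$), so
estimation is by Gibbs sampling: 6000 iterations by default, second half
retained, posterior means and equal-tailed credible intervals reported,
genes ranked by $|\text{posterior mean}|$. Binary responses use probit data
augmentation with one-sided truncated-normal latent draws. See the methods
vignette (`vignettes/network-constrained-bayes.Rmd`) for the full
conditionals and design decisions.

## Worked example

Simulate a pathway-structured dataset (10 star pathways × 5 genes, 3 of
them carrying signal, n = 100) and fit:

```r
library(bnreg)

sim <- simulate_pathway_data(seed = 1)
fit <- bnr_fit(sim$expression, sim$response, sim$network, seed = 1)
fit
#> <bnr_fit> gaussian model: 100 samples, 50 genes
#> chain: 6000 iterations, burn-in 3000, 3000 retained draws
#> posterior means: sigma2 = 0.7928, r = 437.1, lambda2 = 4.195e-06
#> top genes by |posterior mean coefficient|:
#> # A tibble: 5 × 6
#>   gene_id  rank post_mean post_sd ci_lower ci_upper
#>   <chr>   <int>     <dbl>   <dbl>    <dbl>    <dbl>
#> 1 P2G1        1     1.16   0.0587    1.04     1.27
#> 2 P1G1        2     1.11   0.0562    0.997    1.22
#> 3 P3G1        3     0.996  0.0527    0.897    1.10
#> 4 P2G4        4     0.614  0.0487    0.524    0.721
#> 5 P2G2        5     0.604  0.0474    0.514    0.701
```

The three active hubs (`P1G1`, `P2G1`, `P3G1`, true effect 1) head the
ranking; the next rows are their satellites (true effect $1/\sqrt{4} = 0.5$
after degree scaling), each with a 95% credible interval excluding zero.
`sigma2` estimates the residual variance (truth 1 here), `r` the overall
penalty weight, `lambda2` the rate controlling the local scales. Selecting
as many genes as the truth has active recovers the support exactly:

```r
active <- names(sim$true_beta)[sim$true_beta != 0]
mean(active %in% select_top_k(fit, length(active)))
#> [1] 1
b <- tidy(fit)
cor(b$estimate[match(names(sim$true_beta), b$term)], sim$true_beta)
#> [1] 0.9938373
```

`tidy(fit)` gives the broom-style per-gene table, `glance(fit)` a one-row
chain summary, `autoplot(fit)` the coefficient-interval plot,
`plot_trace(fit)` the log-joint and hyperparameter traces, and
`predict(fit, new_expression)` predictions (probit probabilities for
`family = "binary"`).

A thin command-line wrapper covers the same pipeline from the shell:

```sh
Rscript inst/cli/bnr.R simulate --out-dir data --seed 1
Rscript inst/cli/bnr.R fit --expression data/expression.tsv \
    --response data/response.tsv --network data/network.tsv --out-dir out
```

writing a ranking table, log-joint trace, run summary and a JSON manifest
that records everything needed to reproduce the run.

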