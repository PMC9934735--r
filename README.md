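# gcdiff — geometry-complete denoising diffusion for 3D molecules

`gcdiff` generates 3D molecules — atom coordinates, element types and formal
charges jointly — with a denoising diffusion model whose denoiser is an
SE(3)-equivariant, chirality-aware graph network. It is written for people
who work on generative models of molecular structure: it provides the full
pipeline (data model and XYZ/SDF I/O, variance-preserving schedules,
forward/reverse diffusion on the zero-centre-of-mass subspace, a
frame-based denoising network trained by noise prediction, variational
likelihoods, property-conditional generation, diffusion-based molecule
optimization, and the standard valency-based quality metrics) as an R
package with a compiled RcppArmadillo core for the message-passing layers,
scaled so that every stage trains and runs on a single CPU in minutes.

## The model in brief

A molecule is $\mathcal{M} = [X, H]$ with coordinates
$X \in \mathbb{R}^{N\times 3}$ and invariant features $H$ (scaled one-hot
element types + scaled charge). The forward process is variance-preserving
noising, $q(z_t \mid z_0) = \mathcal{N}(\alpha_t z_0, \sigma_t^2 I)$ with
$\alpha_t^2 + \sigma_t^2 = 1$, applied jointly to $[z^{(x)}, z^{(h)}]$ with
$z^{(x)}$ confined to the subspace $\sum_i x_i = 0$ (translation-invariant
likelihoods). The reverse process is $\epsilon$-parametrized: a denoiser
$\Phi$ predicts the injected noise, the clean latent is recovered as
$\tilde z_0 = z_t/\alpha_t - \hat\epsilon\,\sigma_t/\alpha_t$, and the true
posterior $q(z_s \mid z_t, \tilde z_0)$ is sampled. Training minimizes
$\tfrac12\lVert\epsilon - \hat\epsilon\rVert^2$ at uniformly drawn steps.

The denoiser carries invariant scalar and equivariant vector channels per
node. Per directed edge it builds the local frame
$a = \widehat{x_i - x_j}$, $b = \widehat{x_i \times x_j}$, $c = a\times b$
and scalarizes vector features by projection onto it: $b$ is a
pseudo-vector, so the network distinguishes mirror images (chirality);
with frames disabled it is provably reflection-blind. Each edge message is
multiplied by a learned sigmoid gate (scalar message attention). Both
ablations are configuration flags. See the methods vignette
(`vignettes/geometry-complete-diffusion.Rmd`) for assumptions, parameter
meanings and numerical choices.

## Worked example

Train a small model on the built-in synthetic fixtures (four rigid
templates — methane-like, water-like, hydrogen-cyanide-like, and a chiral
five-atom scaffold — jittered by 0.05 Å and randomly rotated), then sample
and score:

```r
library(gcdiff)

mols <- sample_dataset(make_templates(), n = 2000, jitter_sd = 0.05, seed = 0)
sch  <- make_schedule("polynomial", T_steps = 500)
net  <- denoiser_network(
  denoiser_config(n_layers = 4, node_scalar_dim = 64,
                  node_vector_channels = 16, edge_scalar_dim = 32,
                  edge_vector_channels = 8, hidden_dim = 128,
                  self_cond = FALSE),
  seed = 0, T_ref = sch$T)
net <- train_denoiser(mols, net, sch, epochs = 150, batch_size = 32,
                      lr = 1e-3, lr_final = 1e-4, seed = 0)

set.seed(1)
samples <- sample_molecules(net, 500, size_dist = net$size_dist,
                            schedule = sch)
tm <- template_match(samples)
mean(!is.na(tm$template))            # fraction matching a template composition
median(tm$rmsd[is.finite(tm$rmsd)])  # aligned RMSD to the matched template, A
batch_report(samples, toy_bond_table(), with_validity = FALSE)
```

On one CPU this trains in ~9 minutes and samples in ~1.5; a run of the
above printed

```
[1] 0.926
[1] 0.06031615
    n atom_stable mol_stable valid valid_unique novel
1 500    98.41026         96    NA           NA    NA
```

i.e. 92.6% of the 500 generated molecules reproduce a template's exact
element multiset, the median aligned RMSD to the matched ideal template is
0.06 Å (the training jitter alone produces ~0.09 Å), and 96% of samples
are stable molecules under the fixture bond table (every atom at its
allowed valency, bonds inferred from inter-atomic distances). The `NA`
columns appear because RDKit-backed validity scoring was switched off in
this call; `cmd_evaluate()` fills them.

Conditional models (`condition_dim = 1`, `property = "radius_of_gyration"`
in `train_denoiser()`) steer generation toward a target property value, and
`optimize_molecules()` re-uses them to refine existing molecules by
noising to an intermediate step and denoising back under the target
condition — `evaluate_optimization()` reports the before/after property
MAE and molecule-stability deltas.

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/gcdiff.R fixtures --out data/ --n 2000 --jitter 0.05 --seed 0
Rscript inst/cli/gcdiff.R train    --config run.yaml --checkpoint model.rds
Rscript inst/cli/gcdiff.R sample   --checkpoint model.rds --n 100 --out out.xyz
Rscript inst/cli/gcdiff.R optimize --checkpoint cond.rds --input out.xyz \
                                   --target 0.9 --out opt.sdf
Rscript inst/cli/gcdiff.R evaluate --input opt.sdf --out report.json
```

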