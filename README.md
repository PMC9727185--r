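# snareid

SNARE proteins mediate vesicle fusion, and telling them apart from the
broader family of vesicular transport proteins is a recurring binary
classification task in protein function annotation. `snareid` is an R
toolkit for this kind of sequence classification problem. It provides:

- **188-D physicochemical descriptors.** Each sequence of length *L* is
  summarized by 20 amino-acid composition features *F<sub>i</sub> =
  n<sub>i</sub>/L*, plus — for each of 8 physicochemical properties that
  partition the 20 residues into three groups — 3 composition features
  *C<sub>Ai</sub>/L*, 15 distribution features (positions of the first,
  25%, 50%, 75% and last occurrence of each group, divided by *L*), and 3
  transition features (cross-group adjacent pairs over *L − 1*). Total:
  20 + 8 × 21 = 188.
- **SMOTE class balancing.** Minority-class feature rows are oversampled by
  interpolation: `x_new = x + u (x_n − x)` with `u ~ U(0,1)` and `x_n` one of
  the `k` nearest minority neighbors of `x`.
- **The GHKNN classifier.** For each class, the test point's *k* nearest
  class members define a local hyperplane through their centroid. In a
  kernel-induced feature space, the hyperplane coefficients α solve the
  positive-definite system

      (K(V̄,V̄) + λI + μL) α = K(V̄, x̄)

  where `x̄ = x − N̄` and `V̄ = V − N̄` are centered by the neighborhood
  centroid, K is an RBF Gram matrix `exp(−γ‖·‖²)`, and L is the unnormalized
  graph Laplacian of RBF similarities among the neighbors (the graph
  regularizer couples coefficients of similar neighbors). The squared
  distance to the class-c hyperplane is

      dist_c = K(x̄,x̄) + αᵀ K(V̄,V̄) α − 2 K(V̄,x̄)ᵀ α

  and the predicted class is `argmin_c dist_c`. With a linear kernel and
  μ = 0 this reduces exactly to the classical input-space HKNN baseline,
  which is also exported (`hknn_distance`). Tuned defaults: λ = 0.01,
  γ = 2⁻¹⁵, μ = 0.1, k = 10.
- **Evaluation.** SN, SP, ACC and MCC from pooled confusion counts over
  stratified cross-validation folds, one-parameter-at-a-time sweeps over
  λ/γ/μ, and an end-to-end pipeline with provenance logging.
- **Synthetic data.** Seeded generators for labeled sequence populations
  with a controllable residue-composition bias, and for Gaussian feature
  clusters, so the whole pipeline is testable without curated datasets.

## Worked example

```r
library(snareid)

# a biased synthetic dataset standing in for curated SNARE / non-SNARE sets
set <- generate_labeled_set(n_pos = 60, n_neg = 200, bias_strength = 3, seed = 42)
X <- extract_features(set$records)       # 260 x 188 descriptor matrix
round(X[1, 1:6], 4)
#>     f1     f2     f3     f4     f5     f6
#> 0.0204 0.0816 0.0000 0.0306 0.1122 0.0204

bal <- balance_dataset(X, set$labels, seed = 42)   # SMOTE to majority count
table(bal$y)
#> neg pos
#> 200 200

report <- cross_validate(bal$X, bal$y, ghknn_params(), n_folds = 5,
                         seed = 42, positive_label = "pos")
report
#> SN = 1.0000  SP = 0.9900  ACC = 0.9950  MCC = 0.9900
#> (TP = 200, TN = 198, FP = 2, FN = 0)
```

`f1..f20` are the residue frequencies (here f5 = 0.1122 means 11.2% F in the
first synthetic sequence, which is hydrophobically biased); SN/SP are the
positive/negative recall, ACC the overall accuracy, and MCC the Matthews
correlation over the pooled 5-fold confusion table — 0.99 here because a
bias_strength of 3 makes the two populations nearly separable in 188-D
space. On unbiased populations (`bias_strength = 0`) the same pipeline
yields |MCC| ≈ 0, as it should.

A parameter sweep reruns the same cross-validation while varying one of
λ, γ, μ:

```r
sweep_parameter(X, set$labels, ghknn_params(), which = "lam",
                grid = c(0.01, 1, 20), n_folds = 5, seed = 42,
                positive_label = "pos")
#>   value    sn sp   acc   mcc
#> 1  0.01 0.983  1 0.996 0.989
#> 2  1.00 0.983  1 0.996 0.989
#> 3 20.00 1.000  1 1.000 1.000
```

(On this easy synthetic set the sweep is flat; the ranking of λ values is a
property of the dataset, not of the harness.)

## Command line

A single entry point with subcommands wires the same operations together
(`inst/cli/snareid` is an installable Rscript wrapper):

```sh
snareid simulate --n-pos 60 --n-neg 200 --bias 3 --seed 42 \
        --out synth.fasta --labels labels.tsv
snareid extract  --in synth.fasta --labels labels.tsv --out feats.tsv
snareid balance  --in feats.tsv --out feats_bal.tsv --k 5 --seed 7
snareid eval     --in feats.tsv --out metrics.json --positive pos --seed 1
snareid sweep    --in feats.tsv --param lam --grid 0.01,1,20 --out sweep.csv
snareid run      --config config.json --mu 0.5       # flags override the file
```

Every run appends a provenance line (command, parameters, seed, input
digests) to a log, and `run` emits a metrics JSON that is reproducible from
its logged config and seed.

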