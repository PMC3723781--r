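# edafrag

Coarse-grained protein structure prediction by fragment assembly in torsion
space, with an estimation-of-distribution algorithm (EDA) steering the
search: per-window fragment selection probabilities are iteratively
re-estimated from the lowest-energy models of earlier rounds, so later
rounds concentrate on the fragments that good models actually use.

Intended for researchers in structural bioinformatics who want a compact,
fully testable implementation of distribution-guided fragment assembly —
the iterative driver, the sampler, and the standard decoy-set diagnostics —
with the energy function left as a pluggable contract.

## The algorithm

A target of length *L* has a library of candidate fragments per sequence
window (9-mers, then 3-mers for refinement). Window *w* carries a
probability vector *p* over its *m* fragments.

1. Round 1: *p* is uniform (every fragment selected with probability
   *1/m*). Each round builds 25% of the total model budget; every model
   starts from the extended conformation and is assembled by
   fragment insertion under simulated annealing plus iterated hill
   climbing, fragments drawn by roulette wheel from *p*.
2. After each round, the lowest-energy 10% of all models so far form the
   sample set. For each window, the observed usage frequency *f_i* of
   fragment *i* is counted from the models' provenance records.
3. The selection probabilities are updated with a conservation rate
   *k* (default 0.6):

   *p_i(t+1) = k · p_i(t) + (1 − k) · f_i(t)*

4. Repeat for 4 rounds (defaults; all configurable).

Because low-energy models over-use native-like fragments, probability mass
migrates onto them; the package's diagnostics quantify this as
anti-correlation between selection probability and fragment RMSD to
native, falling probability-weighted fragment RMSD, shifting energy/RMSD
histograms, and near-native enrichment among the lowest energies.

## Worked example

A synthetic 36-residue target with 25 fragments per window (one planted
near-native fragment among noisy decoys) and a perfectly funneled oracle
energy (CA RMSD to the hidden native):

```r
library(edafrag)

fx <- make_fixture(fixture_spec(seed = 1))
state <- run_eda(fx$sequence, fx$library, oracle_scorer(fx$native),
                 config = eda_config(budget = 400, iterations = 4),
                 seed = 1)
print(state)
#> Iterative fragment-assembly run: 400 models over 4 iterations (seed 1)
#>   iteration 1: 100 models, energy min    0.202 mean    0.695
#>   iteration 2: 100 models, energy min    0.201 mean    0.331
#>   iteration 3: 100 models, energy min    0.158 mean    0.344
#>   iteration 4: 100 models, energy min    0.201 mean    0.310

tab <- fragment_native_rmsd(fx$library, fx$native)
round(weighted_rmsd_by_iteration(state, tab), 2)
#> [1] 3.80 3.18 2.89 2.68

near_native_enrichment(state, fx$native, n_lowest = 100, cutoff = 3)
#> [1] 100

bs <- blind_select(state, top_n = 5, native = fx$native)
round(c(first = bs$first_rmsd, best_of_5 = bs$best_rmsd), 4)
#>     first best_of_5
#>    0.1576    0.1576
```

Mean model energy (here equal to CA RMSD, in Å) falls from 0.70 at round 1
to 0.31 at round 4; the expected RMSD of a drawn fragment falls from
3.80 Å (uniform) to 2.68 Å (learned); all 100 lowest-energy models are
within 3 Å of the native; and blind energy-ranked selection picks a
0.16 Å model.

The same pipeline is scriptable from a shell via the installed entry
point:

```sh
EXEC=$(Rscript -e 'cat(system.file("exec", "edafrag", package = "edafrag"))')
Rscript $EXEC fixtures -o fx --length 36 --frags 25 --seed 7
Rscript $EXEC run -c config.yaml
Rscript $EXEC analyze RUNDIR
```

`run` writes a manifest (model id, iteration, energy, RMSD to native),
per-iteration probability checkpoints, per-model PDBs and a log;
`analyze` writes the diagnostic report tables.

## Layout

* `R/`, `src/` — fragment I/O, torsion-space conformations and compiled
  geometry kernels (NeRF chain building, Kabsch RMSD), score functions,
  sampler, EDA driver, diagnostics, synthetic benchmark generator, command
  layer.
* `vignettes/distribution-guided-fragment-assembly.Rmd` — methods and
  design notes: parameter meanings, provenance rules, what the synthetic
  benchmark does and does not demonstrate.
* `tests/testthat/` — unit, property and acceptance tests, including
  independent oracles (quaternion superposition, two-pass Pearson,
  interval-overwrite provenance replay).
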