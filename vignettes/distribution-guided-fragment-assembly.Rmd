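---
title: "Distribution-guided fragment assembly: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-guided fragment assembly: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Fragment assembly predicts a protein backbone by replacing the torsions of
short sequence windows with candidate fragments excised from known
structures, searching in torsion space for low-energy arrangements. Because
the landscape is rugged, many models must be generated independently and
most of the computation is wasted on basins that were already explored.

This package implements an estimation-of-distribution variant of that
search. Instead of treating every model build as independent, the selection
probability of each fragment is learned across rounds:

1. Every window of the target starts with a uniform probability vector over
   its candidate fragments (`init_pmfs()`).
2. A round builds a fixed fraction of the total model budget (default 25%,
   i.e. 4 rounds) with `build_model()`. Every model starts from the
   extended conformation (phi = -150, psi = +150, omega = 180 degrees);
   fragments are drawn by roulette wheel from the current per-window
   probability vectors.
3. The lowest-energy fraction of the cumulative model set (default 10%) is
   selected as the *sample set* (`select_sample_set()`), and the observed
   per-window fragment usage frequencies `f_i` are counted from the models'
   provenance maps (`estimate_frequencies()`).
4. Each window's probability vector is updated with the conservation-rate
   mixture `p_i <- k * p_i + (1 - k) * f_i`, with `k = 0.6` by default
   (`update_pmf()`). `k = 1` disables learning entirely; `k = 0` adopts the
   observed frequencies outright.

The update is the whole method: if low-energy models use a fragment more
often than chance, that fragment is probably native-like, and raising its
selection probability concentrates later rounds around it. Everything else
(annealing, hill climbing, scoring) is standard machinery that the update
plugs into.

## Sampling

One model build (`build_model()`) assembles 9-mers first, then 3-mers. Each
stage runs one simulated-annealing pass (Metropolis acceptance,
geometric cooling) followed by one iterated-hill-climbing pass (greedy
descent with roulette-driven proposals, interrupted by unconditional "kick"
insertions between restarts, best-ever model kept). Proposals always pick a
window uniformly at random and a fragment by `roulette_select()`.

Defaults (all in `sampler_config()`):

| parameter | default | meaning |
|---|---|---|
| `sa_steps_per_window` | 20 | annealing moves per window of the stage |
| `t_start`, `t_end` | 2, 0.02 | annealing temperatures (energy units) |
| `ihc_steps_per_window` | 10 | greedy moves per window per restart |
| `n_restarts`, `kick_size` | 3, 2 | hill-climbing rounds and kick strength |
| `refine_t_scale` | 0.1 | 3-mer stage temperature scale |

The temperatures are on the scale of the configured score function; the
defaults suit both shipped scorers, whose typical energy differences per
insertion are of order 0.1–10.

`refine_t_scale` deserves a note. The two stages are not symmetric: 9-mers
assemble the fold, 3-mers refine it locally. Annealing the 3-mer stage as
hot as the assembly stage lets high-temperature acceptances of noisy 3-mers
re-randomize an already-assembled model, severing the link between the
learned 9-mer distribution and the final model quality — we observed
exactly this with a symmetric schedule: 9-mer-only runs improved strongly
across rounds while two-stage runs barely moved. Scaling the refinement
stage's temperatures down by a factor of 10 restores the intended division
of labour. The 3-mer stage also samples uniformly by default; learning can
be switched on for 3-mers (`learn_3mers`), but the distribution update is
estimated from 9-mer provenance, which is where fold-level signal lives.

## Energies

The original protocol ranks models with an external all-atom force field
and a relaxation step; both are outside this package's scope. The seam is
the `score_function` contract (any deterministic map from backbone
coordinates to a scalar), plus two shipped implementations:

* `reference_scorer()` — native-blind: a soft-sphere CA clash penalty
  (`sum over |i-j| >= 3 of max(0, 4 - d)^2`), a radius-of-gyration
  compactness term `(Rg - 2.2 n^0.38)^2`, and a reward of -1 for each
  CA(i)–CA(i+3) distance in [4.5, 5.5] Å (helical/turn spacing, a
  hydrogen-bond proxy). Weights are configurable.
* `oracle_scorer()` — native-aware test instrument: CA RMSD to a hidden
  native plus optional Gaussian noise. With `sigma = 0` it is a perfect
  funnel, which is the controlled condition for validating that the
  distribution update enriches native fragments when — and only to the
  extent that — the energy is informative. The method inherits the quality
  of whatever energy ranks the sample set.

An optional `refine_hook` in `eda_config()` is applied to each model before
ranking (identity by default); that is where a refinement protocol would
plug in without touching the loop.

## Geometry and provenance

Backbones are ideal-geometry chains (N, CA, C; bond lengths 1.458, 1.525,
1.329 Å; angles 111.2°, 116.2°, 121.7°) built from torsions by the standard
NeRF construction in compiled code, with the first residue in a fixed
canonical frame so builds are bitwise deterministic. Dihedral measurement
inverts the construction to ~1e-13 degrees; torsions are canonicalized to
(-180, 180] with -180 mapped to +180 so serialization round trips are
exact. CA RMSD is reflection-guarded Kabsch superposition; the test suite
cross-checks it against an independent quaternion characteristic-polynomial
oracle at 1e-8.

Provenance — which fragment currently occupies which window — is the
quantity the frequency estimation counts, so its bookkeeping matters. The
rule is last-writer-wins: inserting a fragment records its index at that
window and clears the record of any same-length window whose range overlaps
the insertion (those windows' residues no longer carry a single fragment's
torsions). 9-mer and 3-mer maps are kept separately, so refinement does not
erase the fold-level record. Whether the original method keeps or clears
partially overwritten windows is not documented; this rule is one
consistent choice, isolated in a single internal function, and verified in
tests against an interval-overwrite replay simulator.

## The synthetic benchmark

`make_fixture()` generates the controlled conditions every stage is tested
under, with no external data:

* a hidden native: torsions drawn from helical/strand/coil regimes in
  segments, rejected until no CA pair (≥ 3 residues apart) is closer than
  4 Å;
* a dense library: per window, one planted near-native fragment (native
  torsions + 2° jitter; under 1 Å from the native window) among 24 decoys
  (native torsions + 60° jitter), shuffled so the planted fragment sits at
  a random index.

Defaults are 36 residues, 25 fragments per window, one planted fragment —
the library shape of the published diagnostic figures at a length that
keeps a full 4-round, 400-model run under about two minutes on one CPU.
The acceptance script and the acceptance tests run this benchmark at
exactly those sizes, three seeds each.

What the fixture does *not* emulate: real fragment libraries are built from
homologous structures and have correlated, Ramachandran-distributed errors
rather than isotropic torsion jitter; real natives have non-ideal bond
geometry; real energies are far from a perfect funnel. Passing the
benchmark therefore demonstrates that the machinery works — the update
provably concentrates probability mass on fragments that low-energy models
favour — not that predictions on real targets will reach any particular
accuracy. Runs on real data should use real libraries through
`read_fragment_file()` and a real score function through the
`score_function` contract.

## Numerical and design choices

* **Sample-set base.** "The lowest-energy 10%" can be read per-iteration or
  over the cumulative pool. Default is cumulative (every model is stored in
  the final set, and early discoveries should keep informing the update);
  `sample_base = "iteration"` switches to per-round.
* **Uncovered windows.** If no sample-set model carries provenance at a
  window, its distribution is left unchanged rather than reset to uniform:
  sparse coverage should not destroy learned mass.
  `estimate_frequencies()` itself reports a uniform fallback flagged with
  `covered = 0`, and the driver applies the keep-prior rule.
* **Ties.** Energy ties in sample-set selection and blind selection are
  broken by model id, making both deterministic.
* **Reproducibility.** One master seed per run; per-model seeds are drawn
  up front, so model j is reproducible in isolation and manifests are
  byte-identical regardless of worker count.
* **Degenerate inputs.** Zero-sum probability vectors, empty pools and
  windows, length mismatches, and torsions outside [-180, 180] all raise
  errors naming the offending object; a constant vector makes the
  probability/RMSD correlation undefined and returns `NA` with a warning.

## Diagnostics

The `analysis` functions compute the standard decoy-set readouts:
per-window Pearson correlation between learned selection probabilities and
fragment RMSD to native, probability-weighted fragment RMSD per iteration,
per-iteration energy and RMSD histograms on shared bin edges, the
percentage of near-native models among the 100 lowest energies, blind
first/best-of-5 selection, and mean RMSD over the best pool fractions. All
are emitted as TSV tables by `cmd_analyze()`; nothing is asserted on
rendered plots.

```{r, eval = FALSE}
library(edafrag)
fx <- make_fixture(fixture_spec(seed = 1))
state <- run_eda(fx$sequence, fx$library, oracle_scorer(fx$native),
                 config = eda_config(budget = 400, iterations = 4),
                 seed = 1)
tab <- fragment_native_rmsd(fx$library, fx$native)
weighted_rmsd_by_iteration(state, tab)
near_native_enrichment(state, fx$native)
blind_select(state, top_n = 5, native = fx$native)
```

## Known limitations

* Side chains, centroids and all-atom representations are absent; the
  coarse-grained model is backbone N/CA/C only, and RMSD to native is
  backbone-based.
* The shipped reference scorer is intentionally crude; it makes honest
  (native-blind) runs possible but is not competitive with real force
  fields, and the learned distributions are only as good as the energy
  that ranks the sample set.
* Fragment libraries are read or synthesized, never picked from structure
  databases.
* Parallelism is per-model only (`workers`); there is no distributed
  scheduling or mid-run checkpointing.
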