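#' Uniform initial probability vectors over a library
#'
#' At the first iteration every fragment of a window has the same selection
#' probability 1/m.
#'
#' @param library a [fragment_library] (or a bare list of
#'   [fragment_window]s).
#' @param length fragment length to initialize for when a library is given.
#' @return list of probability vectors, one per window, named by window
#'   start.
#' @export
init_pmfs <- function(library, length = 9L) {
  windows <- if (inherits(library, "fragment_library")) {
    if (length == 9L) library$windows9 else library$windows3
  } else library
  if (!base::length(windows)) stop("no windows to initialize")
  pmfs <- lapply(windows, function(w) {
    m <- base::length(w$fragments)
    if (m < 1L) stop("empty window at start ", w$start)
    rep(1 / m, m)
  })
  names(pmfs) <- vapply(windows, function(w) as.character(w$start),
                        character(1))
  pmfs
}

#' Select the lowest-energy fraction of a model pool
#'
#' Returns the `ceiling(fraction * |pool|)` records with smallest energy.
#' Energy ties are broken by `model_id`, making the selection deterministic.
#'
#' @param pool list of `model_record`s.
#' @param fraction proportion in (0, 1].
#' @return list of `model_record`s (the sample set).
#' @export
select_sample_set <- function(pool, fraction = 0.1) {
  if (!length(pool)) stop("empty model pool")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  energies <- vapply(pool, function(m) m$energy, numeric(1))
  ids <- vapply(pool, function(m) as.integer(m$model_id), integer(1))
  k <- ceiling(fraction * length(pool))
  pool[order(energies, ids)[seq_len(k)]]
}

#' Observed fragment usage frequencies at a window
#'
#' For one window, the fraction of sample-set models whose recorded 9-mer
#' provenance at that window is each fragment index; models with no fragment
#' recorded there are excluded from the denominator. If no model covers the
#' window the uniform vector is returned as a fallback (callers that prefer
#' to keep the prior distribution can test coverage with the `covered`
#' attribute).
#'
#' @param sample list of `model_record`s (the sample set).
#' @param window a [fragment_window].
#' @return frequency vector aligned to `window$fragments`, summing to 1,
#'   with attribute `covered` = number of models contributing.
#' @export
estimate_frequencies <- function(sample, window) {
  if (!length(sample)) stop("empty sample set")
  m <- length(window$fragments)
  key <- as.character(window$start)
  slot <- if (window$length == 9L) "provenance9" else "provenance3"
  counts <- numeric(m)
  covered <- 0L
  for (rec in sample) {
    fi <- unname(rec[[slot]][key])
    if (length(fi) == 1L && !is.na(fi)) {
      counts[fi] <- counts[fi] + 1
      covered <- covered + 1L
    }
  }
  f <- if (covered > 0L) counts / covered else rep(1 / m, m)
  attr(f, "covered") <- covered
  f
}

#' Conservation-rate mixture update of a probability vector
#'
#' The estimation-of-distribution update: the new selection probability of
#' fragment i is `k * p_i + (1 - k) * f_i`, where `p` is the current
#' probability, `f` the observed frequency in the sample set, and `k` the
#' conservation rate (default 0.6). `k = 1` keeps the old distribution,
#' `k = 0` adopts the observed frequencies outright. Normalization is
#' preserved exactly (k*1 + (1-k)*1 = 1).
#'
#' @param pmf current probability vector (normalized).
#' @param freqs observed frequency vector (normalized, same length).
#' @param k conservation rate in \[0, 1\].
#' @return updated probability vector.
#' @export
update_pmf <- function(pmf, freqs, k = 0.6) {
  if (length(pmf) != length(freqs))
    stop("pmf and frequency vector lengths differ (",
         length(pmf), " vs ", length(freqs), ")")
  if (!(k >= 0 && k <= 1)) stop("conservation rate k must be in [0, 1]")
  as.numeric(k * pmf + (1 - k) * freqs)
}

#' Iterative-run configuration
#'
#' Defaults follow the published protocol: 4 iterations each generating 25%
#' of the final model set, the lowest-energy 10% as the sample set, and
#' conservation rate k = 0.6.
#'
#' @param budget total number of models across all iterations; must split
#'   evenly over `iterations`.
#' @param iterations number of rounds.
#' @param sample_fraction lowest-energy fraction used to estimate fragment
#'   frequencies.
#' @param k conservation rate of the distribution update.
#' @param sample_base `"cumulative"` (sample set drawn from all models so
#'   far, the default: every model is stored in the final set and earlier
#'   discoveries keep informing the update) or `"iteration"` (current
#'   iteration only).
#' @param sampler a [sampler_config].
#' @param refine_hook optional function `model_record -> model_record`
#'   applied to each model before ranking (identity by default); the seam
#'   where an all-atom refinement step would plug in.
#' @param workers parallel workers for model builds (results are
#'   independent of this number; each model has its own derived seed).
#' @return a list of class `eda_config`.
#' @export
eda_config <- function(budget = 400L, iterations = 4L,
                       sample_fraction = 0.1, k = 0.6,
                       sample_base = c("cumulative", "iteration"),
                       sampler = sampler_config(),
                       refine_hook = NULL, workers = 1L) {
  sample_base <- match.arg(sample_base)
  budget <- as.integer(budget)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("need at least one iteration")
  if (budget < iterations) stop("budget must be >= iterations")
  if (budget %% iterations != 0L)
    stop("budget (", budget, ") must split evenly over ", iterations,
         " iterations")
  if (!(sample_fraction > 0 && sample_fraction <= 1))
    stop("sample_fraction must be in (0, 1]")
  if (!(k >= 0 && k <= 1)) stop("k must be in [0, 1]")
  structure(list(budget = budget, iterations = iterations,
                 sample_fraction = sample_fraction, k = k,
                 sample_base = sample_base, sampler = sampler,
                 refine_hook = refine_hook,
                 workers = as.integer(workers)),
            class = "eda_config")
}

# Per-model seeds derived from the master seed by one upfront draw, so model
# j is reproducible in isolation and results do not depend on worker count
# or build order.
.derive_model_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.build_with_seed <- function(seed, sequence, library, pmfs9, pmfs3,
                             score_fn, config, geometry) {
  set.seed(seed)
  build_model(sequence, library, pmfs9, pmfs3, score_fn,
              config$sampler, geometry)
}

#' Run the iterative estimation-of-distribution prediction
#'
#' The core loop. Each iteration builds `budget / iterations` models with
#' [build_model()] under the current per-window probability vectors
#' (iteration 1 uses the uniform [init_pmfs()]; every model starts from the
#' extended conformation), stores them in the cumulative pool, selects the
#' lowest-energy `sample_fraction` as the sample set, and updates each 9-mer
#' window's probabilities with [update_pmf()] from the sample set's observed
#' fragment usage. Windows that no sample-set model covers keep their
#' current distribution. With `iterations = 1` the loop degenerates to
#' plain independent sampling under uniform probabilities.
#'
#' @param sequence target amino-acid string.
#' @param library a [fragment_library].
#' @param score_fn a [score_function] used both for Metropolis sampling and
#'   for ranking models in the estimation step.
#' @param config an [eda_config].
#' @param seed master seed; every random choice in the run derives from it.
#' @param geometry an [ideal_geometry].
#' @return an object of class `eda_state`: `pool` (all `model_record`s,
#'   tagged with `iteration` and `model_id`), `pmfs9` (final distributions),
#'   `pmfs9_by_iteration` (the distributions *used* at each iteration, entry
#'   1 being uniform), `pmfs3` (uniform unless 3-mer learning is enabled),
#'   `config`, `seed`.
#' @export
run_eda <- function(sequence, library, score_fn = reference_scorer(),
                    config = eda_config(), seed = 1L,
                    geometry = ideal_geometry()) {
  n_iter <- config$iterations
  per_iter <- config$budget %/% n_iter
  model_seeds <- .derive_model_seeds(seed, config$budget)

  pmfs9 <- init_pmfs(library, 9L)
  pmfs3 <- if (length(library$windows3)) init_pmfs(library, 3L) else NULL
  learn3 <- isTRUE(config$sampler$learn_3mers)

  pool <- vector("list", config$budget)
  pmfs9_by_iteration <- vector("list", n_iter)
  pmfs3_by_iteration <- if (learn3) vector("list", n_iter) else NULL

  apply_fun <- if (config$workers > 1L &&
                   requireNamespace("parallel", quietly = TRUE)) {
    function(idx, f) parallel::mclapply(idx, f, mc.cores = config$workers)
  } else {
    function(idx, f) lapply(idx, f)
  }

  for (t in seq_len(n_iter)) {
    pmfs9_by_iteration[[t]] <- pmfs9
    if (learn3) pmfs3_by_iteration[[t]] <- pmfs3
    ids <- ((t - 1L) * per_iter + 1L):(t * per_iter)
    models <- apply_fun(ids, function(j) {
      rec <- .build_with_seed(model_seeds[j], sequence, library, pmfs9,
                              if (learn3) pmfs3 else NULL,
                              score_fn, config, geometry)
      rec$model_id <- j
      rec$iteration <- t
      if (!is.null(config$refine_hook)) rec <- config$refine_hook(rec)
      rec
    })
    pool[ids] <- models

    base <- switch(config$sample_base,
                   cumulative = pool[seq_len(max(ids))],
                   iteration = models)
    sample_set <- select_sample_set(base, config$sample_fraction)

    update_set <- function(pmfs, windows) {
      for (i in seq_along(windows)) {
        f <- estimate_frequencies(sample_set, windows[[i]])
        if (attr(f, "covered") > 0L)
          pmfs[[i]] <- update_pmf(pmfs[[i]], as.numeric(f), config$k)
        # uncovered windows keep their current distribution
      }
      pmfs
    }
    pmfs9 <- update_set(pmfs9, library$windows9)
    if (learn3) pmfs3 <- update_set(pmfs3, library$windows3)
  }

  structure(list(iteration = n_iter, pmfs9 = pmfs9, pmfs3 = pmfs3,
                 pmfs9_by_iteration = pmfs9_by_iteration,
                 pmfs3_by_iteration = pmfs3_by_iteration,
                 pool = pool, config = config, seed = seed),
            class = "eda_state")
}

#' @export
print.eda_state <- function(x, ...) {
  e <- vapply(x$pool, function(m) m$energy, numeric(1))
  it <- vapply(x$pool, function(m) m$iteration, integer(1))
  cat("Iterative fragment-assembly run:", length(x$pool), "models over",
      x$iteration, "iterations (seed", paste0(x$seed, ")\n"))
  for (t in sort(unique(it))) {
    cat(sprintf("  iteration %d: %3d models, energy min %8.3f mean %8.3f\n",
                t, sum(it == t), min(e[it == t]), mean(e[it == t])))
  }
  invisible(x)
}

#' Manifest table of a run's model pool
#'
#' @param state an `eda_state` (or bare list of `model_record`s).
#' @param native optional native `conformation` or CA matrix; adds a
#'   `rmsd_native` column.
#' @return data.frame with columns model_id, iteration, energy and
#'   optionally rmsd_native.
#' @export
pool_manifest <- function(state, native = NULL) {
  pool <- if (inherits(state, "eda_state")) state$pool else state
  out <- data.frame(
    model_id = vapply(pool, function(m) as.integer(m$model_id), integer(1)),
    iteration = vapply(pool, function(m) as.integer(m$iteration),
                       integer(1)),
    energy = vapply(pool, function(m) m$energy, numeric(1)))
  if (!is.null(native)) {
    nat <- .as_ca(native)
    out$rmsd_native <- vapply(pool, function(m)
      ca_rmsd(m$conformation, nat), numeric(1))
  }
  out
}
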