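#' Roulette-wheel (fitness-proportionate) fragment selection
#'
#' Draws a fragment index from a probability vector: index `i` is returned
#' with probability `probs[i]`. This is the single point where the learned
#' distribution influences the sampling.
#'
#' @param probs non-negative probability vector (need not be normalized, but
#'   the learned distributions always are); a zero-sum vector is an error.
#' @return 1-based index into `probs`.
#' @export
roulette_select <- function(probs) {
  total <- sum(probs)
  if (!is.finite(total) || total <= 0)
    stop("probabilities must sum to a positive number")
  if (any(probs < 0)) stop("negative probability")
  cs <- cumsum(probs)
  u <- runif(1L) * total
  which(cs >= u)[1L]
}

#' Simulated-annealing schedule
#'
#' Geometric cooling from `t_start` to `t_end` over `n_steps` move attempts
#' (temperatures in energy units).
#'
#' @param t_start,t_end start and end temperatures, `t_start >= t_end > 0`.
#' @param n_steps number of move attempts, >= 1.
#' @return an object of class `annealing_schedule`; `$cooling` holds the
#'   per-step geometric factor.
#' @export
annealing_schedule <- function(t_start = 2, t_end = 0.02, n_steps = 100L) {
  if (!(t_start >= t_end && t_end > 0)) stop("need t_start >= t_end > 0")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  cooling <- if (n_steps > 1L) (t_end / t_start)^(1 / (n_steps - 1L)) else 1
  structure(list(t_start = t_start, t_end = t_end, n_steps = n_steps,
                 cooling = cooling), class = "annealing_schedule")
}

#' Metropolis acceptance decision
#'
#' Accepts an energy change `delta_e` at temperature `temp`: always when
#' `delta_e <= 0`, else with probability `exp(-delta_e / temp)`.
#'
#' @param delta_e proposed energy change.
#' @param temp temperature, > 0.
#' @return logical.
#' @export
metropolis_accept <- function(delta_e, temp) {
  delta_e <= 0 || runif(1L) < exp(-delta_e / temp)
}

# Internal sampler state: raw torsion matrix + cached coords/energy +
# provenance for the active fragment length. Avoids rebuilding conformation
# objects inside the move loop.
.sampler_state <- function(conf, score_fn, len) {
  slot <- if (len == 9L) "provenance9" else "provenance3"
  list(torsions = conf$torsions,
       coords = conf$coords,
       energy = score_fn$fn(conf$coords),
       prov = conf[[slot]])
}

.state_into_conf <- function(conf, state, len) {
  slot <- if (len == 9L) "provenance9" else "provenance3"
  conf$torsions <- state$torsions
  conf$coords <- state$coords
  conf[[slot]] <- state$prov
  conf
}

# One proposed insertion: pick a window uniformly, a fragment by roulette,
# and evaluate. `accept_fn(delta_e)` decides; returns the updated state.
.propose_move <- function(state, windows, pmfs, score_fn, geom, len,
                          accept_fn) {
  wi <- sample.int(length(windows), 1L)
  w <- windows[[wi]]
  fi <- roulette_select(pmfs[[wi]])
  rows <- w$start:(w$start + len - 1L)
  old <- state$torsions[rows, , drop = FALSE]
  state$torsions[rows, ] <- w$fragments[[fi]]$torsions
  coords <- build_backbone_cpp(state$torsions, geom$bonds, geom$angles)
  e <- score_fn$fn(coords)
  if (accept_fn(e - state$energy)) {
    state$energy <- e
    state$coords <- coords
    state$prov <- .update_provenance(state$prov, w$start, len, fi)
  } else {
    state$torsions[rows, ] <- old
  }
  state
}

#' Simulated-annealing stage of a model build
#'
#' Runs `schedule$n_steps` fragment-insertion attempts: a window chosen
#' uniformly at random, a fragment drawn from that window's probability
#' vector by [roulette_select()], Metropolis acceptance with geometrically
#' cooling temperature.
#'
#' @param conf starting `conformation`.
#' @param windows list of same-length [fragment_window]s.
#' @param pmfs list of probability vectors aligned to `windows`.
#' @param score_fn a [score_function].
#' @param schedule an [annealing_schedule].
#' @return the final `conformation` (provenance updated for the stage's
#'   fragment length).
#' @export
sa_stage <- function(conf, windows, pmfs, score_fn, schedule) {
  len <- windows[[1L]]$length
  geom <- conf$geometry
  state <- .sampler_state(conf, score_fn, len)
  temp <- schedule$t_start
  accept <- function(de) metropolis_accept(de, temp)
  for (s in seq_len(schedule$n_steps)) {
    state <- .propose_move(state, windows, pmfs, score_fn, geom, len,
                           accept)
    temp <- temp * schedule$cooling
  }
  .state_into_conf(conf, state, len)
}

#' Iterated-hill-climbing stage of a model build
#'
#' `n_restarts` rounds of a greedy phase (only non-worsening insertions are
#' accepted, proposals still roulette-driven) followed by a perturbation
#' "kick" of `kick_size` random insertions accepted unconditionally, which
#' lets the search leave the current basin. The best conformation ever seen
#' is tracked and returned, so the returned energy never exceeds the input
#' energy.
#'
#' @inheritParams sa_stage
#' @param n_restarts number of greedy+kick rounds.
#' @param n_steps greedy move attempts per round.
#' @param kick_size insertions per perturbation.
#' @return the best-ever `conformation`.
#' @export
ihc_stage <- function(conf, windows, pmfs, score_fn, n_restarts = 3L,
                      n_steps = 100L, kick_size = 2L) {
  len <- windows[[1L]]$length
  geom <- conf$geometry
  state <- .sampler_state(conf, score_fn, len)
  best <- state
  greedy <- function(de) de <= 0
  always <- function(de) TRUE
  for (r in seq_len(n_restarts)) {
    for (s in seq_len(n_steps)) {
      state <- .propose_move(state, windows, pmfs, score_fn, geom, len,
                             greedy)
    }
    if (state$energy < best$energy) best <- state
    if (kick_size > 0L && r < n_restarts) {
      for (k in seq_len(kick_size)) {
        state <- .propose_move(state, windows, pmfs, score_fn, geom, len,
                               always)
      }
    }
  }
  if (state$energy < best$energy) best <- state
  .state_into_conf(conf, best, len)
}

#' Sampler configuration
#'
#' Tuning knobs for one model build. Step counts scale with the number of
#' windows of the active fragment length; temperatures are in the (unitless)
#' energy scale of the configured score function.
#'
#' @param sa_steps_per_window SA move attempts per window.
#' @param ihc_steps_per_window greedy move attempts per window per restart.
#' @param n_restarts hill-climbing restarts.
#' @param kick_size perturbation insertions between restarts.
#' @param t_start,t_end annealing temperatures (9-mer assembly stage).
#' @param refine_t_scale temperature scale of the 3-mer stage relative to
#'   the 9-mer stage. The 9-mer stage assembles the fold; the 3-mer stage
#'   refines it locally, and annealing it as hot as the assembly stage would
#'   undo the assembled structure.
#' @param learn_3mers if `TRUE`, the 3-mer stage uses learned probability
#'   vectors too; by default 3-mers are drawn uniformly and only 9-mer usage
#'   feeds the distribution update.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(sa_steps_per_window = 20L,
                           ihc_steps_per_window = 10L,
                           n_restarts = 3L, kick_size = 2L,
                           t_start = 2, t_end = 0.02,
                           refine_t_scale = 0.1,
                           learn_3mers = FALSE) {
  structure(list(sa_steps_per_window = as.integer(sa_steps_per_window),
                 ihc_steps_per_window = as.integer(ihc_steps_per_window),
                 n_restarts = as.integer(n_restarts),
                 kick_size = as.integer(kick_size),
                 t_start = t_start, t_end = t_end,
                 refine_t_scale = refine_t_scale,
                 learn_3mers = isTRUE(learn_3mers)),
            class = "sampler_config")
}

.uniform_pmfs <- function(windows) {
  lapply(windows, function(w) {
    m <- length(w$fragments)
    rep(1 / m, m)
  })
}

#' Build one coarse-grained model
#'
#' Starts from the extended conformation and assembles 9-mers, then 3-mers:
#' for each fragment length, one simulated-annealing stage followed by one
#' iterated-hill-climbing stage. Fragment choice is driven by the supplied
#' probability vectors (`pmfs3 = NULL` means uniform 3-mer sampling, the
#' default behaviour unless `config$learn_3mers` is set by the caller
#' providing learned `pmfs3`).
#'
#' @param sequence target amino-acid string.
#' @param library a [fragment_library] covering the sequence.
#' @param pmfs9 list of probability vectors aligned to `library$windows9`.
#' @param pmfs3 as `pmfs9` for 3-mers, or `NULL` for uniform.
#' @param score_fn a [score_function].
#' @param config a [sampler_config].
#' @param geometry an [ideal_geometry].
#' @return an object of class `model_record`: fields `conformation`,
#'   `energy` (the score of the returned conformation), `provenance9`,
#'   `provenance3`, and `model_id`/`iteration` slots filled by the
#'   iterative driver.
#' @export
build_model <- function(sequence, library, pmfs9 = NULL, pmfs3 = NULL,
                        score_fn = reference_scorer(),
                        config = sampler_config(),
                        geometry = ideal_geometry()) {
  if (library$target_length != nchar(sequence))
    stop("library target length (", library$target_length,
         ") != sequence length (", nchar(sequence), ")")
  if (length(library$windows9) == 0L)
    stop("library has no 9-mer windows")
  if (is.null(pmfs9)) pmfs9 <- .uniform_pmfs(library$windows9)
  conf <- extended_conformation(sequence, geometry)

  run_stages <- function(conf, windows, pmfs, t_scale = 1) {
    nw <- length(windows)
    sched <- annealing_schedule(config$t_start * t_scale,
                                config$t_end * t_scale,
                                max(1L, config$sa_steps_per_window * nw))
    conf <- sa_stage(conf, windows, pmfs, score_fn, sched)
    ihc_stage(conf, windows, pmfs, score_fn,
              n_restarts = config$n_restarts,
              n_steps = max(1L, config$ihc_steps_per_window * nw),
              kick_size = config$kick_size)
  }

  conf <- run_stages(conf, library$windows9, pmfs9)
  if (length(library$windows3)) {
    if (is.null(pmfs3)) pmfs3 <- .uniform_pmfs(library$windows3)
    conf <- run_stages(conf, library$windows3, pmfs3,
                       t_scale = config$refine_t_scale %||% 0.1)
  }

  structure(list(model_id = NA_integer_, iteration = NA_integer_,
                 conformation = conf,
                 energy = score_fn$fn(conf$coords),
                 provenance9 = conf$provenance9,
                 provenance3 = conf$provenance3),
            class = "model_record")
}

#' @export
print.model_record <- function(x, ...) {
  cat("Model", x$model_id, "(iteration", paste0(x$iteration, "):"),
      "energy", format(x$energy, digits = 4), "with",
      length(x$provenance9), "nine-mer fragments recorded\n")
  invisible(x)
}
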