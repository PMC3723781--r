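#' Per-fragment CA RMSD to the native structure
#'
#' For every fragment of every window, builds the fragment's backbone
#' standalone under ideal geometry and superposes its alpha carbons on the
#' native structure's corresponding window. Because the fragment is rebuilt
#' with ideal geometry while a real native need not be ideal, a fragment
#' whose torsions equal the native's measures slightly above zero; for
#' ideal-geometry natives it is numerically zero.
#'
#' @param library a [fragment_library].
#' @param native a `conformation`, 3n x 3 backbone matrix, or n x 3 CA
#'   matrix covering the whole target.
#' @param length fragment length to tabulate (9 or 3).
#' @param geometry an [ideal_geometry] for fragment rebuilding.
#' @return list of class `fragment_rmsd_table`: one non-negative numeric
#'   vector per window (aligned to fragment indices), named by window start.
#' @export
fragment_native_rmsd <- function(library, native, length = 9L,
                                 geometry = ideal_geometry()) {
  windows <- if (length == 9L) library$windows9 else library$windows3
  native_ca <- if (inherits(native, "conformation")) {
    ca_coords(native)
  } else {
    m <- as.matrix(native)
    if (nrow(m) == 3L * library$target_length) ca_coords(m) else m
  }
  if (nrow(native_ca) < library$target_length)
    stop("native does not cover the target (", nrow(native_ca), " CA for ",
         library$target_length, " residues)")
  out <- lapply(windows, function(w) {
    rows <- w$start:(w$start + w$length - 1L)
    nat_win <- native_ca[rows, , drop = FALSE]
    vapply(w$fragments, function(f) {
      frag_ca <- ca_coords(build_coords(f$torsions, geometry))
      kabsch_rmsd_cpp(frag_ca, nat_win)
    }, numeric(1))
  })
  names(out) <- vapply(windows, function(w) as.character(w$start),
                       character(1))
  class(out) <- "fragment_rmsd_table"
  out
}

#' Pearson correlation between selection probability and fragment RMSD
#'
#' A learned distribution that favours native-like fragments shows
#' anti-correlation (negative r) between each fragment's selection
#' probability and its RMSD to the native.
#'
#' @param pmf probability vector of a window.
#' @param rmsds that window's fragment RMSD vector, same length (>= 3).
#' @return Pearson r in \[-1, 1\], or `NA` (with a warning) when either
#'   vector is constant.
#' @export
probability_rmsd_correlation <- function(pmf, rmsds) {
  if (length(pmf) != length(rmsds)) stop("vectors differ in length")
  if (length(pmf) < 3L) stop("need at least 3 fragments")
  if (stats::sd(pmf) == 0 || stats::sd(rmsds) == 0) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  cor(pmf, rmsds)
}

#' Probability-weighted average fragment RMSD of a window
#'
#' `sum_i p_i * rmsd_i`: the expected RMSD-to-native of the fragment drawn
#' at this window. Uniform probabilities give the plain mean; a point mass
#' gives that fragment's RMSD. Falling values across iterations show the
#' distribution concentrating on native-like fragments.
#'
#' @param pmf probability vector.
#' @param rmsds fragment RMSD vector, same length.
#' @return weighted RMSD in Angstrom.
#' @export
weighted_fragment_rmsd <- function(pmf, rmsds) {
  if (length(pmf) != length(rmsds)) stop("vectors differ in length")
  sum(pmf * rmsds)
}

#' Window-averaged probability-weighted fragment RMSD per iteration
#'
#' Convenience wrapper over a finished run: for each iteration's
#' distributions, [weighted_fragment_rmsd()] per window, averaged over
#' windows.
#'
#' @param state an `eda_state`.
#' @param rmsd_table a `fragment_rmsd_table` from [fragment_native_rmsd()].
#' @return numeric vector, one mean weighted RMSD per iteration.
#' @export
weighted_rmsd_by_iteration <- function(state, rmsd_table) {
  vapply(state$pmfs9_by_iteration, function(pmfs) {
    mean(vapply(seq_along(pmfs), function(i)
      weighted_fragment_rmsd(pmfs[[i]], rmsd_table[[i]]), numeric(1)))
  }, numeric(1))
}

.pool_energies <- function(pool) vapply(pool, function(m) m$energy,
                                        numeric(1))
.pool_ids <- function(pool) vapply(pool, function(m)
  as.integer(m$model_id), integer(1))
.pool_rmsds <- function(pool, native) {
  nat <- .as_ca(native)
  vapply(pool, function(m) ca_rmsd(m$conformation, nat), numeric(1))
}

#' Near-native percentage among the lowest-energy models
#'
#' Selects the `n_lowest` lowest-energy models of a pool and reports the
#' percentage whose CA RMSD to the native is below `cutoff` (the standard
#' decoy-set enrichment readout; 100 models and 3 A by convention).
#'
#' @param pool list of `model_record`s (or an `eda_state`).
#' @param native native `conformation` or CA matrix.
#' @param n_lowest number of lowest-energy models to inspect.
#' @param cutoff RMSD threshold in Angstrom.
#' @return percentage in \[0, 100\].
#' @export
near_native_enrichment <- function(pool, native, n_lowest = 100L,
                                   cutoff = 3) {
  if (inherits(pool, "eda_state")) pool <- pool$pool
  if (is.null(native)) stop("native structure required")
  if (length(pool) < n_lowest)
    stop("pool has ", length(pool), " models, need >= ", n_lowest)
  ord <- order(.pool_energies(pool), .pool_ids(pool))
  low <- pool[ord[seq_len(n_lowest)]]
  100 * mean(.pool_rmsds(low, native) < cutoff)
}

#' Energy-driven blind selection of predictions
#'
#' The blind protocol: the *first prediction* is the lowest-energy model;
#' the *best prediction* is, among the `top_n` lowest-energy models, the one
#' closest to the native (the native is used only for this retrospective
#' report, never for the selection itself). Energy ties are broken by
#' `model_id`. By construction the best prediction's RMSD never exceeds the
#' first prediction's.
#'
#' @param pool list of `model_record`s (or an `eda_state`).
#' @param top_n number of lowest-energy candidates for the best prediction.
#' @param native native `conformation` or CA matrix; `NULL` returns the
#'   first prediction only.
#' @return list with `first` (model_record), `first_rmsd`, and when a
#'   native is given `best` and `best_rmsd`.
#' @export
blind_select <- function(pool, top_n = 5L, native = NULL) {
  if (inherits(pool, "eda_state")) pool <- pool$pool
  if (length(pool) < top_n)
    stop("pool has ", length(pool), " models, need >= ", top_n)
  ord <- order(.pool_energies(pool), .pool_ids(pool))
  first <- pool[[ord[1L]]]
  out <- list(first = first, first_rmsd = NA_real_,
              best = NULL, best_rmsd = NA_real_)
  if (is.null(native)) return(out)
  top <- pool[ord[seq_len(top_n)]]
  rmsds <- .pool_rmsds(top, native)
  out$first_rmsd <- rmsds[[1L]]
  best_i <- which.min(rmsds)
  out$best <- top[[best_i]]
  out$best_rmsd <- rmsds[[best_i]]
  out
}

#' Quality summary over the best fractions of a pool
#'
#' For each fraction q, the mean CA RMSD to native of the
#' `ceiling(q * |pool|)` lowest-RMSD models (q = 0.001 is the conventional
#' "1 per mille" readout), plus the single best model's RMSD.
#'
#' @param pool list of `model_record`s (or an `eda_state`).
#' @param native native `conformation` or CA matrix.
#' @param fractions proportions in (0, 1].
#' @return data.frame with columns fraction, n_models, mean_rmsd; the single
#'   best RMSD is attached as attribute `best_rmsd`.
#' @export
summarize_quality <- function(pool, native,
                              fractions = c(0.001, 0.01, 0.1, 1)) {
  if (inherits(pool, "eda_state")) pool <- pool$pool
  if (!length(pool)) stop("empty pool")
  rmsds <- sort(.pool_rmsds(pool, native))
  rows <- lapply(fractions, function(q) {
    k <- ceiling(q * length(rmsds))
    data.frame(fraction = q, n_models = k, mean_rmsd = mean(rmsds[seq_len(k)]))
  })
  out <- do.call(rbind, rows)
  attr(out, "best_rmsd") <- rmsds[[1L]]
  out
}

#' Per-iteration histograms of energy or RMSD
#'
#' Shared bin edges across iterations so distribution shifts are directly
#' comparable (the histogram-shift diagnostic: later iterations concentrating
#' at lower energy / lower RMSD).
#'
#' @param pool list of `model_record`s (or an `eda_state`) tagged by
#'   iteration.
#' @param field `"energy"` or `"rmsd"`.
#' @param bins number of bins.
#' @param native required when `field = "rmsd"`.
#' @return list with `breaks`, `counts` (iterations x bins matrix, rows
#'   named by iteration) and `means` (per-iteration mean of the field).
#' @export
histogram_by_iteration <- function(pool, field = c("energy", "rmsd"),
                                   bins = 20L, native = NULL) {
  if (inherits(pool, "eda_state")) pool <- pool$pool
  field <- match.arg(field)
  values <- if (field == "energy") .pool_energies(pool) else {
    if (is.null(native)) stop("native required for RMSD histograms")
    .pool_rmsds(pool, native)
  }
  iters <- vapply(pool, function(m) as.integer(m$iteration), integer(1))
  all_iters <- seq_len(max(iters))
  breaks <- seq(min(values), max(values), length.out = bins + 1L)
  counts <- t(vapply(all_iters, function(t) {
    v <- values[iters == t]
    if (!length(v)) return(integer(bins))
    hist(v, breaks = breaks, plot = FALSE)$counts
  }, integer(bins)))
  rownames(counts) <- all_iters
  means <- vapply(all_iters, function(t) {
    v <- values[iters == t]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  list(breaks = breaks, counts = counts, means = means)
}
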