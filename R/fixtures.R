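#' Specification of a synthetic benchmark target
#'
#' The synthetic generator plants a controlled funnel: a hidden native
#' torsion path, and per window one near-native fragment (native torsions
#' plus small jitter) among noisy decoys. Every other module is testable
#' against it with no external data. Defaults emulate the standard library
#' shape of 25 candidate fragments per window; 36 residues keeps a full
#' 4-iteration run with a few hundred models desk-scale.
#'
#' @param length target length in residues (>= 9).
#' @param frags_per_window candidate fragments per window (>= 2).
#' @param native_frac number of near-native fragments planted per window.
#' @param torsion_noise_sd decoy jitter s.d. in degrees around the native
#'   torsions.
#' @param jitter_sd near-native jitter s.d. in degrees.
#' @param seed generator seed; fixtures are a pure function of this spec.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(length = 36L, frags_per_window = 25L,
                         native_frac = 1L, torsion_noise_sd = 60,
                         jitter_sd = 2, seed = 1L) {
  length <- as.integer(length)
  frags_per_window <- as.integer(frags_per_window)
  if (length < 9L) stop("length must be >= 9")
  if (frags_per_window < 2L) stop("need at least 2 fragments per window")
  if (native_frac < 1L || native_frac >= frags_per_window)
    stop("native_frac must be in [1, frags_per_window)")
  structure(list(length = length, frags_per_window = frags_per_window,
                 native_frac = as.integer(native_frac),
                 torsion_noise_sd = torsion_noise_sd,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Draw one native torsion path from secondary-structure-like regimes:
# helical segments around (-60, -45), strand segments around (-120, 130),
# and broad coil. Omega fixed at 180 (trans).
.draw_native_torsions <- function(n) {
  phi <- numeric(n)
  psi <- numeric(n)
  i <- 1L
  while (i <= n) {
    seg <- min(sample(4:10, 1L), n - i + 1L)
    type <- sample(c("helix", "strand", "coil"), 1L,
                   prob = c(0.45, 0.35, 0.2))
    idx <- i:(i + seg - 1L)
    if (type == "helix") {
      phi[idx] <- -60 + rnorm(seg, 0, 4)
      psi[idx] <- -45 + rnorm(seg, 0, 4)
    } else if (type == "strand") {
      phi[idx] <- -120 + rnorm(seg, 0, 6)
      psi[idx] <- 130 + rnorm(seg, 0, 6)
    } else {
      phi[idx] <- runif(seg, -150, -60)
      psi[idx] <- runif(seg, 60, 170)
    }
    i <- i + seg
  }
  cbind(phi = phi, psi = psi, omega = rep(180, n))
}

.has_ca_clash <- function(coords, cutoff = 4.0) {
  ca <- ca_coords(coords)
  n <- nrow(ca)
  for (i in seq_len(n - 3L)) {
    d <- sqrt(rowSums((ca[(i + 3L):n, , drop = FALSE] -
                         matrix(ca[i, ], n - i - 2L, 3L, byrow = TRUE))^2))
    if (any(d < cutoff)) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic native structure
#'
#' Samples per-residue torsions from helical/strand/coil regimes and rejects
#' chains with any CA pair (three or more residues apart) closer than 4 A,
#' so the hidden native is clash-free under the reference scorer.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [fixture_spec].
#' @param max_tries rejection-loop cap.
#' @return list with `sequence` (random 20-letter string), `torsions`
#'   (n x 3) and `native` (a `conformation`).
#' @export
make_native <- function(spec, max_tries = 500L) {
  set.seed(spec$seed)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sequence <- paste(sample(letters20, spec$length, replace = TRUE),
                    collapse = "")
  geometry <- ideal_geometry()
  for (try in seq_len(max_tries)) {
    torsions <- .draw_native_torsions(spec$length)
    coords <- build_coords(torsions, geometry)
    if (!.has_ca_clash(coords)) {
      native <- conformation(sequence, torsions, geometry)
      return(list(sequence = sequence, torsions = native$torsions,
                  native = native))
    }
  }
  stop("could not generate a clash-free native in ", max_tries,
       " attempts (length ", spec$length, ")")
}

.jittered_fragment <- function(native_torsions, rows, sd, tag) {
  tor <- native_torsions[rows, , drop = FALSE] +
    matrix(rnorm(3L * length(rows), 0, sd), length(rows), 3L)
  fragment(canonicalize_torsion(tor), source_tag = tag)
}

.make_windows <- function(spec, native_torsions, len) {
  n_windows <- spec$length - len + 1L
  lapply(seq_len(n_windows), function(start) {
    rows <- start:(start + len - 1L)
    m <- spec$frags_per_window
    frags <- vector("list", m)
    for (i in seq_len(spec$native_frac)) {
      frags[[i]] <- .jittered_fragment(
        native_torsions, rows, spec$jitter_sd,
        sprintf("nat%d A %d", i, start))
    }
    for (i in (spec$native_frac + 1L):m) {
      frags[[i]] <- .jittered_fragment(
        native_torsions, rows, spec$torsion_noise_sd,
        sprintf("s%03d A %d", i, start))
    }
    ord <- sample.int(m)
    w <- fragment_window(start, frags[ord])
    attr(w, "planted_index") <- match(seq_len(spec$native_frac), ord)
    w
  })
}

#' Generate a fragment library with planted near-native fragments
#'
#' For every 9-mer and 3-mer window, `native_frac` fragments are the native
#' torsions with small jitter (`jitter_sd`, default 2 degrees) and the rest
#' are decoys jittered with `torsion_noise_sd` (default 60 degrees).
#' Fragment order is shuffled per window so the planted fragments sit at
#' random indices; each window carries its planted indices in the
#' `planted_index` attribute (a synthetic-benchmark convenience that real
#' libraries do not have).
#'
#' @param spec a [fixture_spec].
#' @param native output of [make_native()] (or a matrix of native torsions).
#' @return a [fragment_library] densely covering the target.
#' @export
make_library <- function(spec, native) {
  torsions <- if (is.list(native)) native$torsions else as.matrix(native)
  set.seed(spec$seed + 104729L) # decouple library stream from native stream
  fragment_library(spec$length,
                   windows9 = .make_windows(spec, torsions, 9L),
                   windows3 = .make_windows(spec, torsions, 3L))
}

#' Generate a complete synthetic benchmark target
#'
#' @param spec a [fixture_spec].
#' @return list with `spec`, `sequence`, `native` (a `conformation`) and
#'   `library` (a [fragment_library]).
#' @export
make_fixture <- function(spec = fixture_spec()) {
  nat <- make_native(spec)
  library <- make_library(spec, nat)
  list(spec = spec, sequence = nat$sequence, native = nat$native,
       library = library)
}
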