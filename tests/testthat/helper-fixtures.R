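# Small in-code fixtures shared across test files. Kept tiny: the full
# study-scale benchmark lives only in test-acceptance.R.

tiny_spec <- function(seed = 3L) {
  fixture_spec(length = 18L, frags_per_window = 8L, torsion_noise_sd = 60,
               seed = seed)
}

tiny_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- make_fixture(tiny_spec(seed))
    cache[[key]]
  }
})

# A deterministic two-window 9-mer library for I/O round trips.
two_window_library <- function() {
  set.seed(42)
  mk <- function(tag) {
    fragment(matrix(round(runif(27, -179, 179), 3), 9, 3), source_tag = tag)
  }
  w1 <- fragment_window(1L, list(mk("1abc A 5"), mk("2def B 12")))
  w2 <- fragment_window(4L, list(mk("3ghi C 101")))
  list(w1, w2)
}

# Hand-built pool of bare-bones model records with prescribed energies,
# iterations and provenance; conformation omitted unless coords given.
fake_record <- function(id, energy, iteration = 1L, prov9 = integer(0),
                        conf = NULL) {
  structure(list(model_id = as.integer(id), iteration = as.integer(iteration),
                 conformation = conf, energy = energy,
                 provenance9 = prov9, provenance3 = integer(0)),
            class = "model_record")
}
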