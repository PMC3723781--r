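test_that("initial distributions are uniform over each window", {
  fx <- tiny_fixture()
  pmfs <- init_pmfs(fx$library, 9L)
  expect_length(pmfs, length(fx$library$windows9))
  for (p in pmfs) {
    expect_equal(p, rep(1 / 8, 8))
    expect_equal(sum(p), 1)
  }
  w25 <- fragment_window(1L, replicate(25, fragment(matrix(0, 9, 3)),
                                       simplify = FALSE))
  expect_equal(init_pmfs(list(w25))[[1]], rep(0.04, 25))
  w1 <- fragment_window(1L, list(fragment(matrix(0, 9, 3))))
  expect_equal(init_pmfs(list(w1))[[1]], 1)
})

test_that("sample-set selection takes the lowest energies with stable ties", {
  pool <- lapply(1:10, function(i) fake_record(i, energy = 11 - i))
  sel <- select_sample_set(pool, 0.1)
  expect_length(sel, 1L)
  expect_equal(sel[[1]]$model_id, 10L) # energy 1
  expect_length(select_sample_set(pool, 1.0), 10L)
  # ties broken by model id
  tied <- lapply(1:4, function(i) fake_record(5 - i, energy = 7))
  sel <- select_sample_set(tied, 0.5)
  expect_equal(sort(vapply(sel, `[[`, integer(1), "model_id")), 1:2)
  expect_error(select_sample_set(list(), 0.1), "empty")
  expect_error(select_sample_set(pool, 0), "fraction")
})

test_that("sample-set selection matches a brute-force sort oracle", {
  set.seed(81)
  pool <- lapply(1:100, function(i) fake_record(i, energy = rnorm(1)))
  sel <- select_sample_set(pool, 0.1)
  oracle_ids <- vapply(pool, `[[`, integer(1), "model_id")[
    order(vapply(pool, `[[`, numeric(1), "energy"))][1:10]
  expect_setequal(vapply(sel, `[[`, integer(1), "model_id"), oracle_ids)
})

test_that("frequency estimation counts window provenance over covering models", {
  w <- fragment_window(4L, replicate(4, fragment(matrix(0, 9, 3)),
                                     simplify = FALSE))
  sample <- list(fake_record(1, 0, prov9 = c("4" = 1L)),
                 fake_record(2, 0, prov9 = c("4" = 1L)),
                 fake_record(3, 0, prov9 = c("4" = 2L)),
                 fake_record(4, 0, prov9 = integer(0)))
  f <- estimate_frequencies(sample, w)
  expect_equal(as.numeric(f), c(2 / 3, 1 / 3, 0, 0))
  expect_equal(attr(f, "covered"), 3L)
  expect_equal(sum(f), 1)
  # all models agreeing on one fragment
  unanimous <- lapply(1:3, function(i) fake_record(i, 0, prov9 = c("4" = 4L)))
  expect_equal(as.numeric(estimate_frequencies(unanimous, w)), c(0, 0, 0, 1))
  # nobody covers the window: uniform fallback, flagged by covered = 0
  f0 <- estimate_frequencies(list(fake_record(1, 0)), w)
  expect_equal(as.numeric(f0), rep(0.25, 4))
  expect_equal(attr(f0, "covered"), 0L)
})

test_that("the conservation-rate update follows the mixture formula exactly", {
  # independent arithmetic oracle for p' = k p + (1-k) f
  mixture_oracle <- function(p, f, k) {
    out <- numeric(length(p))
    for (i in seq_along(p)) out[i] <- k * p[i] + (1 - k) * f[i]
    out
  }
  p <- rep(0.04, 25)
  f <- c(1, rep(0, 24))
  got <- update_pmf(p, f, k = 0.6)
  expect_equal(got, mixture_oracle(p, f, 0.6), tolerance = 1e-15)
  expect_equal(got[1], 0.424)
  expect_equal(got[2], 0.024)
  expect_equal(sum(got), 1, tolerance = 1e-12)

  set.seed(82)
  for (rep in 1:20) {
    m <- sample(2:30, 1)
    p <- runif(m); p <- p / sum(p)
    f <- runif(m); f <- f / sum(f)
    k <- runif(1)
    expect_equal(update_pmf(p, f, k), mixture_oracle(p, f, k),
                 tolerance = 1e-12)
    expect_equal(sum(update_pmf(p, f, k)), 1, tolerance = 1e-12)
  }
})

test_that("conservation-rate limits: k=1 conserves, k=0 adopts frequencies", {
  p <- c(0.7, 0.2, 0.1)
  f <- c(0, 0.5, 0.5)
  expect_identical(update_pmf(p, f, 1), p)
  expect_identical(update_pmf(p, f, 0), f)
  expect_error(update_pmf(p, c(0.5, 0.5), 0.6), "lengths differ")
  expect_error(update_pmf(p, f, 1.2), "k must be")
})

test_that("run configuration validates the budget split", {
  expect_error(eda_config(budget = 10, iterations = 4), "split evenly")
  expect_error(eda_config(budget = 2, iterations = 4), "budget")
  expect_error(eda_config(sample_fraction = 0), "sample_fraction")
  cfg <- eda_config(budget = 8, iterations = 4)
  expect_equal(cfg$k, 0.6)
  expect_equal(cfg$sample_fraction, 0.1)
})

# One small shared run exercised by several assertions below.
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiny_fixture()
      cache <<- list(
        fx = fx,
        state = run_eda(fx$sequence, fx$library, oracle_scorer(fx$native),
                        config = eda_config(budget = 48, iterations = 4,
                                            sampler = sampler_config(
                                              sa_steps_per_window = 10L,
                                              ihc_steps_per_window = 5L)),
                        seed = 5))
    }
    cache
  }
})

test_that("every distribution stays normalized across a full run", {
  st <- small_run()$state
  for (t in seq_along(st$pmfs9_by_iteration)) {
    for (p in st$pmfs9_by_iteration[[t]]) {
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
  for (p in st$pmfs9) expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("models are tagged by iteration and stored exactly once", {
  st <- small_run()$state
  man <- pool_manifest(st)
  expect_equal(nrow(man), 48L)
  expect_equal(sort(unique(man$iteration)), 1:4)
  expect_equal(unname(table(man$iteration)), rep(12L, 4),
               ignore_attr = TRUE)
  expect_equal(man$model_id, 1:48)
})

test_that("probability mass migrates towards planted native fragments", {
  run <- small_run()
  fx <- run$fx
  st <- run$state
  planted <- vapply(seq_along(fx$library$windows9), function(i)
    attr(fx$library$windows9[[i]], "planted_index")[1], integer(1))
  mass <- vapply(st$pmfs9_by_iteration, function(pmfs)
    mean(vapply(seq_along(pmfs), function(i) pmfs[[i]][planted[i]],
                numeric(1))), numeric(1))
  # non-decreasing up to numerical noise, and strictly enriched overall
  expect_true(all(diff(mass) > -1e-9))
  expect_gt(mass[4], mass[1])
})

test_that("a single iteration degenerates to independent uniform sampling", {
  fx <- tiny_fixture()
  st <- run_eda(fx$sequence, fx$library, oracle_scorer(fx$native),
                config = eda_config(budget = 6, iterations = 1,
                                    sampler = sampler_config(
                                      sa_steps_per_window = 5L,
                                      ihc_steps_per_window = 2L)),
                seed = 9)
  expect_length(st$pmfs9_by_iteration, 1L)
  for (p in st$pmfs9_by_iteration[[1]]) expect_equal(p, rep(1 / 8, 8))
})

test_that("k=1 leaves every distribution untouched across iterations", {
  fx <- tiny_fixture()
  st <- run_eda(fx$sequence, fx$library, oracle_scorer(fx$native),
                config = eda_config(budget = 16, iterations = 4, k = 1,
                                    sampler = sampler_config(
                                      sa_steps_per_window = 5L,
                                      ihc_steps_per_window = 2L)),
                seed = 10)
  uniform <- rep(1 / 8, 8)
  for (t in 1:4) {
    for (p in st$pmfs9_by_iteration[[t]]) expect_equal(p, uniform)
  }
  for (p in st$pmfs9) expect_equal(p, uniform)
})

test_that("k=0 sets each covered window's distribution to the observed frequencies", {
  fx <- tiny_fixture()
  cfg <- eda_config(budget = 16, iterations = 2, k = 0,
                    sampler = sampler_config(sa_steps_per_window = 5L,
                                             ihc_steps_per_window = 2L))
  st <- run_eda(fx$sequence, fx$library, oracle_scorer(fx$native),
                config = cfg, seed = 11)
  # recompute the iteration-1 sample set and frequencies independently
  pool1 <- st$pool[1:8]
  sample1 <- select_sample_set(pool1, 0.1)
  for (i in seq_along(fx$library$windows9)) {
    f <- estimate_frequencies(sample1, fx$library$windows9[[i]])
    expected <- if (attr(f, "covered") > 0) as.numeric(f) else rep(1 / 8, 8)
    expect_equal(st$pmfs9_by_iteration[[2]][[i]], expected)
  }
})

test_that("identical seeds reproduce identical pools", {
  fx <- tiny_fixture()
  cfg <- eda_config(budget = 8, iterations = 2,
                    sampler = sampler_config(sa_steps_per_window = 5L,
                                             ihc_steps_per_window = 2L))
  sfn <- oracle_scorer(fx$native)
  a <- run_eda(fx$sequence, fx$library, sfn, config = cfg, seed = 12)
  b <- run_eda(fx$sequence, fx$library, sfn, config = cfg, seed = 12)
  expect_identical(pool_manifest(a), pool_manifest(b))
  expect_identical(a$pmfs9, b$pmfs9)
  c_ <- run_eda(fx$sequence, fx$library, sfn, config = cfg, seed = 13)
  expect_false(identical(pool_manifest(a)$energy, pool_manifest(c_)$energy))
})
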