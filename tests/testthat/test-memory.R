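test_that("memory preallocates the full chunk space with a bijective index", {
  mem <- new_memory()
  expect_length(mem$c1, 1728L)
  expect_identical(sum(mem$populated), 0L)
  # index_of round-trips for all 1728 triples
  tr <- chunk_triple(1:1728)
  expect_identical(chunk_index(tr$c1, tr$c2, tr$c3), 1:1728)
  # lexicographic, 1-based
  expect_identical(chunk_index(1, 1, 1), 1L)
  expect_identical(chunk_index(12, 12, 12), 1728L)
  expect_identical(chunk_index(1, 1, 2), 2L)
  expect_error(chunk_index(0, 1, 1))
})

test_that("lifetime runs from chunk creation with the fixed offset", {
  expect_equal(lifetime(1, 1, T = 0.05), 0.05)
  expect_equal(lifetime(1, 5, T = 0.05), 4.05)
  # increases by exactly one round per round
  L <- lifetime(3, 3:10)
  expect_equal(diff(L), rep(1, 7))
  expect_error(lifetime(5, 4), "inconsistent")
})

test_that("base-level activation follows the power-law learning curve", {
  expect_equal(base_level(1, 1.05, 0.5), log(2) - 0.5 * log(1.05))
  expect_equal(base_level(1, 1.05, 0.5), 0.6688, tolerance = 1e-4)
  expect_equal(base_level(2, 1.05, 0.5), 1.3620, tolerance = 1e-4)
  # strictly increasing in presentations, decreasing in lifetime
  for (L in c(0.05, 1.05, 7.3, 39.05)) {
    b <- base_level(1:6, L, 0.5)
    expect_true(all(diff(b) > 0))
  }
  b <- base_level(3, c(0.5, 1, 2, 10, 40), 0.5)
  expect_true(all(diff(b) < 0))
  expect_error(base_level(0, 1, 0.5), "corrupt")
  expect_error(base_level(1, 0, 0.5), "corrupt")
})

test_that("similarity is the ratio dissimilarity, zero only at equality", {
  expect_identical(similarity(9, 9), 0)
  expect_equal(similarity(6, 9), -1 / 3)
  expect_equal(similarity(1, 12), -11 / 12)
  g <- expand.grid(a = 1:12, b = 1:12)
  s <- similarity(g$a, g$b)
  expect_true(all(s <= 0 & s >= -1))
  expect_identical(s == 0, g$a == g$b)
  expect_equal(s, similarity(g$b, g$a))  # symmetric
  expect_error(similarity(0, 3))
})

test_that("context component weights slot mismatches by P", {
  chunk <- list(c2 = 6, c3 = 9)
  expect_equal(context_component(chunk, c(9, 9), P = 12), 12 * (-1 / 3))
  # perfect match has zero penalty at any weighting
  perfect <- list(c2 = 4, c3 = 9)
  for (P in c(0, 1, 12, 35)) {
    expect_identical(context_component(perfect, c(4, 9), P), 0)
  }
  # linear in P
  expect_equal(context_component(chunk, c(9, 9), 24),
               2 * context_component(chunk, c(9, 9), 12))
})

test_that("chunk activation composes base level, context and noise", {
  params <- act_params(tau = -2, P = 10)
  unpop <- list(populated = FALSE)
  expect_identical(chunk_activation(unpop, c(6, 9), params, j = 3), -1000)
  ch <- list(c2 = 6, c3 = 8, n = 1, t = 1, populated = TRUE)
  a0 <- chunk_activation(ch, c(6, 9), params, noise = 0, j = 2)
  expect_equal(a0, 0.6688 + 10 * (0 - 1 / 9), tolerance = 1e-3)
  # additivity in the noise term
  expect_equal(chunk_activation(ch, c(6, 9), params, noise = 0.37, j = 2),
               a0 + 0.37)
  # perfect slot match with zero noise reduces to the base level exactly
  pm <- list(c2 = 6, c3 = 9, n = 2, t = 1, populated = TRUE)
  expect_identical(chunk_activation(pm, c(6, 9), params, j = 5),
                   base_level(2, lifetime(1, 5, params$T), params$d))
})

test_that("retrieval picks the maximally active chunk above threshold", {
  params <- act_params(tau = -2, P = 10)
  mem <- new_memory()
  # fresh memory: everything at the sentinel, nothing retrievable
  r <- retrieve(mem, c(6, 9), params, j = 1)
  expect_false(r$retrieved)
  expect_identical(r$activation, -1000)
  # a single populated chunk above threshold wins
  mem2 <- present(mem, c(7, 6, 9), j = 1)
  r2 <- retrieve(mem2, c(6, 9), params, j = 2)
  expect_true(r2$retrieved)
  expect_identical(r2$index, chunk_index(7, 6, 9))
  # same chunk below threshold: no retrieval
  tight <- act_params(tau = 5, P = 10)
  expect_false(retrieve(mem2, c(6, 9), tight, j = 2)$retrieved)
  expect_error(retrieve(mem2, c(6, 9), params, noise_vector = 0:3, j = 2),
               "noise vector")
})

test_that("activation ties break toward the lowest chunk index", {
  params <- act_params(tau = -10, P = 10)
  mem <- new_memory()
  # two chunks differing only in the workforce slot, presented in the same
  # round: identical base level and context, hence exactly tied
  mem <- present(mem, c(7, 6, 8), j = 1)
  mem <- present(mem, c(5, 6, 8), j = 1)
  r <- retrieve(mem, c(6, 9), params, j = 2)
  expect_identical(r$index, chunk_index(5, 6, 8))
  o <- oracle_retrieve(mem, c(6, 9), params, numeric(1728), j = 2)
  expect_identical(r$index, o$index)
})

test_that("retrieval agrees with a linear-scan oracle on random states", {
  set.seed(42)
  for (rep in 1:200) {
    st <- random_memory_state()
    nz <- rnorm(1728, sd = 0.3)
    r <- retrieve(st$memory, st$request, st$params, nz, st$j)
    o <- oracle_retrieve(st$memory, st$request, st$params, nz, st$j)
    expect_identical(r$retrieved, o$retrieved)
    expect_identical(r$index, o$index)
  }
})

test_that("unpopulated chunks are never retrievable", {
  mem <- new_memory()
  mem <- present(mem, c(3, 3, 3), j = 1)
  # even a deeply negative threshold only admits populated chunks
  params <- act_params(tau = -999, P = 35)
  r <- retrieve(mem, c(12, 9), params, j = 40)
  expect_identical(r$index, chunk_index(3, 3, 3))
})

test_that("presentation creates once then merges, keeping creation round", {
  mem <- present(new_memory(), c(7, 6, 8), j = 1)
  k <- chunk_index(7, 6, 8)
  expect_true(mem$populated[k])
  expect_identical(mem$n[k], 1L)
  expect_identical(mem$t[k], 1L)
  mem2 <- present(mem, c(7, 6, 8), j = 5)
  expect_identical(mem2$n[k], 2L)
  expect_identical(mem2$t[k], 1L)  # lifetime keeps running from creation
  expect_identical(sum(mem2$populated), sum(mem$populated))
  mem3 <- present(mem2, c(1, 1, 1), j = 6)
  expect_identical(sum(mem3$populated), sum(mem2$populated) + 1L)
  expect_error(present(mem, c(0, 6, 8), 2))
})

test_that("transient noise follows the logistic distribution", {
  expect_identical(logistic_noise(0, 10L), numeric(10))
  expect_error(logistic_noise(-0.1), "non-negative")
  set.seed(7)
  z <- logistic_noise(0.2, 1e5L)
  v <- 0.2^2 * pi^2 / 3
  expect_lt(abs(mean(z)), 3 * sqrt(v / 1e5))
  # sample variance against the logistic identity s^2 pi^2 / 3
  expect_lt(abs(var(z) - v), 4 * v * sqrt(3.2 / 1e5))
})
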