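test_that("the Hamiltonian matches hand values and a brute-force oracle", {
  zero <- potts_model(matrix(0, 3, 2))
  expect_equal(hamiltonian(zero, c(1L, 2L, 1L)), 0)

  m2 <- potts_model(matrix(0, 2, 2), e = list("1_2" = rbind(c(1, 0), c(0, 0))))
  expect_equal(hamiltonian(m2, c(1L, 1L)), -1)
  expect_equal(statistical_energy_score(m2, c(1L, 1L)), 1)

  m <- random_potts_model(4, 3, coupling_density = 1, coupling_scale = 0.7,
                          field_scale = 0.4, seed = 12)
  set.seed(2)
  for (k in 1:20) {
    x <- sample.int(3, 4, replace = TRUE)
    expect_equal(hamiltonian(m, x), bf_hamiltonian(m, x))
  }
})

test_that("score ordering matches Boltzmann probability ordering", {
  m <- tiny_potts()
  d <- exact_distribution(m)
  sc <- statistical_energy_score(m, d$states)
  expect_equal(order(sc), order(d$prob))
})

test_that("exact distribution: uniform null, gauge invariance, T limit", {
  zero <- potts_model(matrix(0, 3, 2))
  expect_equal(exact_distribution(zero)$prob, rep(1 / 8, 8))

  m <- tiny_potts()
  d <- exact_distribution(m)
  expect_equal(sum(d$prob), 1)

  shifted <- m
  shifted$h[2, ] <- shifted$h[2, ] + 3.7  # constant shift at one site
  expect_equal(exact_distribution(shifted)$prob, d$prob)

  hot <- exact_distribution(m, temperature = 1e4)
  expect_lt(max(abs(hot$prob - 1 / 8)), 1e-3)

  big <- potts_model(matrix(0, 30, 4))
  expect_error(exact_distribution(big), "guard")
})

test_that("single-site conditionals match the enumerated joint", {
  zero <- potts_model(matrix(0, 2, 3))
  expect_equal(conditional_distribution(zero, c(1L, 1L), 1), rep(1 / 3, 3))

  m <- tiny_potts()
  d <- exact_distribution(m)
  seqv <- c(2L, 1L, 2L)
  for (site in 1:3) {
    others <- setdiff(1:3, site)
    sel <- d$states[, others[1]] == seqv[others[1]] &
      d$states[, others[2]] == seqv[others[2]]
    cond <- d$prob[sel][order(d$states[sel, site])]
    expect_equal(conditional_distribution(m, seqv, site), cond / sum(cond))
  }
  shifted <- m
  shifted$h[1, ] <- shifted$h[1, ] + 2
  expect_equal(conditional_distribution(shifted, seqv, 1),
               conditional_distribution(m, seqv, 1))
  expect_error(conditional_distribution(m, seqv, 5), "site")
})

test_that("Metropolis sampling is uniform under the zero model and never
           rejects downhill moves", {
  zero <- potts_model(matrix(0, 3, 4))
  s <- metropolis_sample(zero, sampling_config(n_steps = 200,
                                               n_chains = 4000, seed = 2),
                         diagnostics = TRUE)
  f <- msa_freq1(s$data, 3, 4)
  expect_lt(max(abs(f - 0.25)), 3 * sqrt(0.25 * 0.75 / 4000))
  expect_equal(attr(s, "diagnostics")$n_downhill_rejected, 0L)

  m <- tiny_potts()
  sm <- metropolis_sample(m, sampling_config(n_steps = 500, n_chains = 500,
                                             seed = 3),
                          diagnostics = TRUE)
  expect_equal(attr(sm, "diagnostics")$n_downhill_rejected, 0L)
  expect_equal(msa_depth(sm), 500L)
})

test_that("the Potts oracle beats the uniform stub on model-generated data", {
  m <- tiny_potts()
  losses <- vapply(1:20, function(s) {
    msa <- metropolis_sample(m, sampling_config(n_steps = 300, n_chains = 40,
                                                seed = s))
    mask <- mask_msa(msa, 0.15, seed = s + 100)$mask
    if (nrow(mask) == 0) return(c(0, 0))
    c(pseudolikelihood_loss(potts_oracle_mlm(m), msa, mask),
      pseudolikelihood_loss(uniform_mlm(), msa, mask))
  }, numeric(2))
  expect_lt(mean(losses[1, ]), mean(losses[2, ]))
})

test_that("the oracle emits uniform logits for the zero model", {
  zero <- potts_model(matrix(0, 3, 2))
  msa <- new_msa(matrix(1L, 2, 3), alphabet = zero$alphabet)
  mk <- mask_msa(msa, 1, seed = 1)
  lg <- potts_oracle_mlm(zero)(mk$masked, mk$mask)
  expect_true(all(lg == 0))
})

test_that("fitting an independent-site model recovers site frequencies in
           closed form", {
  # L = 1: softmax(h) must reproduce the empirical symbol frequencies
  set.seed(5)
  data <- matrix(sample.int(3, 400, replace = TRUE, prob = c(0.6, 0.3, 0.1)))
  msa <- new_msa(data, alphabet = make_alphabet(c("A", "B", "C")))
  fit <- fit_boltzmann_machine(msa, fit_config(lambda = 0, tol = 1e-4,
                                               moments = "exact",
                                               max_sweeps = 3000))
  p <- exp(fit$h[1, ]) / sum(exp(fit$h[1, ]))
  f <- tabulate(data, 3) / 400
  expect_lt(max(abs(p - f)), 1e-3)
})

test_that("the fitter matches data moments and shrinks with regularization", {
  m <- tiny_potts()
  samp <- metropolis_sample(m, sampling_config(n_steps = 800,
                                               n_chains = 4000, seed = 4))
  fit <- fit_boltzmann_machine(samp, fit_config(lambda = 0, tol = 5e-3,
                                                learning_rate = 0.2,
                                                moments = "exact",
                                                max_sweeps = 2000))
  expect_true(attr(fit, "fit")$converged)
  mm <- exact_moments(fit)
  expect_lt(max(abs(mm$f1 - msa_freq1(samp$data, 3, 2))), 1e-2)
  expect_lt(max(abs(mm$f2 - msa_freq2(samp$data, 3, 2))), 1e-2)

  norms <- vapply(c(1e-3, 1e-2, 1e-1, 1), function(lam) {
    f <- suppressWarnings(
      fit_boltzmann_machine(samp, fit_config(lambda = lam, tol = 1e-4,
                                             learning_rate = 0.2,
                                             moments = "exact",
                                             max_sweeps = 300)))
    sum(abs(f$e))
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("the zero-sum gauge leaves the distribution unchanged and zeroes
           the marginals of the parameters", {
  m <- tiny_potts()
  g <- zero_sum_gauge(m)
  expect_equal(exact_distribution(g)$prob, exact_distribution(m)$prob)
  expect_lt(max(abs(rowMeans(g$h))), 1e-12)
  expect_lt(max(abs(rowMeans(g$e[1, 2, , ]))), 1e-12)
  expect_lt(max(abs(colMeans(g$e[1, 2, , ]))), 1e-12)
})

test_that("Potts JSON round-trips exactly", {
  m <- random_potts_model(3, 4, coupling_density = 0.7, seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_potts(m, f)
  back <- read_potts(f)
  expect_equal(back$h, m$h)
  expect_equal(back$e, m$e)
  expect_equal(back$alphabet$symbols, m$alphabet$symbols)
})

test_that("model construction enforces symmetry and finiteness", {
  e_bad <- array(0, c(2, 2, 2, 2)); e_bad[1, 2, 1, 2] <- 1
  expect_error(potts_model(matrix(0, 2, 2), e_bad), "symmetry|e\\[i,j")
  e_self <- array(0, c(2, 2, 2, 2)); e_self[1, 1, 1, 1] <- 1
  expect_error(potts_model(matrix(0, 2, 2), e_self), "self")
  expect_error(potts_model(matrix(c(0, Inf), 1, 2)), "finite")
})
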