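test_that("masking hits the expected cells at the boundary probabilities", {
  pm <- random_profile_msa(8, 6, 1, q = 4, seed = 1)
  mk0 <- mask_msa(pm$msa, 0, seed = 1)
  expect_equal(nrow(mk0$mask), 0L)
  expect_identical(mk0$masked$data, pm$msa$data)

  mk1 <- mask_msa(pm$msa, 1, seed = 1)
  expect_equal(nrow(mk1$mask), 48L)
  expect_true(all(is.na(mk1$masked$data)))

  mkr <- mask_msa(pm$msa, 1, seed = 1, scope = "first_row_fixed_context")
  expect_equal(sort(unique(mkr$mask[, 1])), 1L)
  expect_equal(nrow(mkr$mask), 8L)

  expect_error(mask_msa(pm$msa, 1.2), "\\[0, 1\\]")
})

test_that("masked fraction concentrates at p (binomial bound over seeds)", {
  pm <- random_profile_msa(50, 100, 1, q = 4, seed = 2)
  n_cells <- 100 * 50
  sd3 <- 3 * sqrt(0.1 * 0.9 / n_cells)
  for (s in 1:10) {
    frac <- nrow(mask_msa(pm$msa, 0.1, seed = s)$mask) / n_cells
    expect_lt(abs(frac - 0.1), sd3)
  }
})

test_that("greedy filling takes the argmax with lowest-index ties", {
  ab3 <- make_alphabet(c("A", "B", "C"))
  msa <- new_msa(matrix(c(1L, 1L), 1), alphabet = ab3)
  mk <- mask_msa(msa, 1, seed = 1)
  lg <- array(0, c(1, 2, 3))
  lg[1, , ] <- rbind(c(0, 5, 1), c(2, 2, 0))
  out <- fill_masked(mk$masked, mk$mask, lg)
  expect_equal(out$data[1, ], c(2L, 1L))
})

test_that("softmax filling draws tokens at the closed-form rate", {
  # One masked column over many rows: logits (0, ln 3) => P(symbol 2) = 3/4.
  msa <- new_msa(matrix(1L, 10000, 1), alphabet = ab2)
  mk <- mask_msa(msa, 1, seed = 1)
  lg <- array(rep(c(0, log(3)), each = 10000), c(10000, 1, 2))
  out <- fill_masked(mk$masked, mk$mask, lg, selection = "softmax",
                     t_sel = 1, seed = 4)
  expect_lt(abs(mean(out$data == 2L) - 0.75), 0.02)
})

test_that("softmax selection approaches greedy as temperature vanishes", {
  pm <- random_profile_msa(6, 5, 1, q = 4, seed = 9)
  mk <- mask_msa(pm$msa, 1, seed = 2)
  set.seed(31)
  lg <- array(stats::rnorm(5 * 6 * 4), c(5, 6, 4))
  greedy <- fill_masked(mk$masked, mk$mask, lg)
  cold <- fill_masked(mk$masked, mk$mask, lg, selection = "softmax",
                      t_sel = 1e-6, seed = 11)
  expect_identical(greedy$data, cold$data)
})

test_that("non-finite logits at masked cells violate the model contract", {
  msa <- new_msa(matrix(1L, 2, 2), alphabet = ab2)
  mk <- mask_msa(msa, 1, seed = 1)
  lg <- array(NaN, c(2, 2, 2))
  expect_error(fill_masked(mk$masked, mk$mask, lg), "non-finite")
  bad_model <- new_mlm(function(masked, mask) array(0, c(1, 1, 2)))
  expect_error(iterative_masking(msa, bad_model,
                                 generation_config(p = 1, iterations = 1)),
               "contract")
})

test_that("iterative masking preserves shape, is identity at I=0, and a
           constant model forces its fixed point in one iteration", {
  pm <- random_profile_msa(10, 8, 1, q = 4, seed = 3)
  same <- iterative_masking(pm$msa, uniform_mlm(),
                            generation_config(p = 0.5, iterations = 0))
  expect_identical(same$data, pm$msa$data)

  all_a <- iterative_masking(pm$msa, constant_mlm(c(10, 0, 0, 0)),
                             generation_config(p = 1, iterations = 1))
  expect_true(all(all_a$data == 1L))
  expect_equal(dim(all_a$data), dim(pm$msa$data))
})

test_that("the Potts oracle fills a single masked cell with the exact
           conditional argmax computed by enumeration", {
  m <- tiny_potts()
  d <- exact_distribution(m)
  oracle <- potts_oracle_mlm(m)
  for (row in list(c(1L, 2L, 1L), c(2L, 2L, 2L), c(1L, 1L, 2L))) {
    for (site in 1:3) {
      msa <- new_msa(matrix(row, 1), alphabet = m$alphabet)
      msa$data[1, site] <- NA_integer_
      mask <- cbind(1L, site)
      lg <- oracle(msa, mask)
      # enumeration oracle: condition the exact joint on the other sites
      others <- setdiff(1:3, site)
      sel <- d$states[, others[1]] == row[others[1]] &
        d$states[, others[2]] == row[others[2]]
      cond <- d$prob[sel][order(d$states[sel, site])]
      expect_equal(which.max(lg[1, site, ]), which.max(cond))
      filled <- fill_masked(msa, mask, lg)
      expect_equal(filled$data[1, site], which.max(cond))
    }
  }
})

test_that("full-MSA generation assembles batches to the natural depth and
           is the identity at p = 0 up to plan order", {
  pm <- random_profile_msa(6, 10, 1, q = 4, seed = 4)
  cfg <- generation_config(p = 0, iterations = 3, batch_depth = 4L, seed = 6)
  out <- generate_synthetic_msa(pm$msa, uniform_mlm(), cfg)
  expect_equal(msa_depth(out), 10L)
  plan <- attr(out, "plan")
  expect_length(plan$batches, 3L)
  expect_identical(out$data, pm$msa$data[unlist(plan$batches), ])
  # deterministic given seed
  out2 <- generate_synthetic_msa(pm$msa, uniform_mlm(), cfg)
  expect_identical(out$data, out2$data)
})

test_that("pseudolikelihood loss matches closed forms", {
  pm <- random_profile_msa(4, 3, 1, q = 4, seed = 5)
  mask <- cbind(c(1L, 2L, 3L), c(1L, 2L, 4L))

  # model putting (effectively) all mass on the true symbol => loss 0
  truth <- pm$msa$data
  sharp <- new_mlm(function(masked, mask) {
    lg <- array(-1e4, c(nrow(truth), ncol(truth), 4))
    for (k in seq_len(nrow(mask)))
      lg[mask[k, 1], mask[k, 2], truth[mask[k, 1], mask[k, 2]]] <- 1e4
    lg
  })
  expect_lt(pseudolikelihood_loss(sharp, pm$msa, mask), 1e-6)

  # uniform model: loss = n * ln q
  expect_equal(pseudolikelihood_loss(uniform_mlm(), pm$msa, mask),
               3 * log(4))

  # hand-set logits on a 1x2 MSA with one masked cell
  msa <- new_msa(matrix(c(2L, 1L), 1), alphabet = ab2)
  one <- cbind(1L, 1L)
  stub <- new_mlm(function(masked, mask) {
    lg <- array(0, c(1, 2, 2)); lg[1, 1, ] <- c(1.3, -0.2); lg
  })
  # true symbol at the masked cell is index 2, logit -0.2
  manual <- -((-0.2) - log(exp(1.3) + exp(-0.2)))
  expect_equal(pseudolikelihood_loss(stub, msa, one), manual)

  expect_error(pseudolikelihood_loss(uniform_mlm(), msa,
                                     matrix(integer(0), 0, 2)),
               "at least one")
})
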