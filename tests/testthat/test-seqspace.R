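test_that("Hamming distance matches hand values and is a metric", {
  expect_equal(hamming(c(1L, 2L, 3L), c(1L, 2L, 3L)), 0)
  expect_equal(hamming(1:4, c(4L, 3L, 2L, 1L)), 1)
  a <- as.integer(encode_sequences("AC-A"))
  b <- as.integer(encode_sequences("AAAA"))
  expect_equal(hamming(a, b), 0.5)
  expect_equal(hamming(a, b, normalized = FALSE), 2)
  expect_error(hamming(1:3, 1:4), "equal length")

  set.seed(21)
  for (k in 1:25) {
    x <- sample.int(4, 8, TRUE); y <- sample.int(4, 8, TRUE)
    z <- sample.int(4, 8, TRUE)
    expect_equal(hamming(x, y), hamming(y, x))
    expect_gte(hamming(x, z) + 1e-12, abs(hamming(x, y) - hamming(y, z)))
    expect_lte(hamming(x, z), hamming(x, y) + hamming(y, z) + 1e-12)
    expect_equal(hamming(x, x), 0)
  }
})

test_that("hamming_matrix agrees with the pairwise definition", {
  pm <- random_profile_msa(9, 15, 1, q = 4, seed = 23)
  D <- hamming_matrix(pm$msa)
  for (i in c(1, 7)) for (j in c(3, 15))
    expect_equal(D[i, j], hamming(pm$msa$data[i, ], pm$msa$data[j, ]))
})

test_that("closest-natural lookup matches a brute-force double loop", {
  nat <- random_profile_msa(20, 50, 1, q = 4, seed = 25)$msa
  qry <- random_profile_msa(20, 15, 1, q = 4, seed = 26)$msa
  res <- closest_natural(qry, nat)
  for (m in seq_len(15)) {
    best_d <- Inf; best_i <- NA
    for (n in seq_len(50)) {
      d <- hamming(qry$data[m, ], nat$data[n, ])
      if (d < best_d) { best_d <- d; best_i <- n }
    }
    expect_equal(res$index[m], best_i)
    expect_equal(res$distance[m], best_d)
  }

  # verbatim presence => distance 0
  res0 <- closest_natural(msa_rows(nat, 5), nat)
  expect_equal(res0$distance, 0)
  expect_equal(res0$index, 5)

  # excluding self on a single-sequence MSA leaves no eligible match
  one <- msa_rows(nat, 1)
  expect_error(closest_natural(one, one, exclude_self = TRUE), "eligible")
  nn <- closest_natural(nat, nat, exclude_self = TRUE)
  expect_true(all(nn$index != seq_len(50)) || any(nn$distance > 0))
  expect_true(all(nn$distance > 0 | nn$index != seq_len(50)))
})

test_that("neighbor counts invert to sequence weights exactly", {
  same <- new_msa(matrix(2L, 5, 3), alphabet = ab2)
  expect_equal(neighbor_counts(same), rep(5L, 5))
  far <- new_msa(rbind(rep(1L, 6), rep(2L, 6)), alphabet = ab2)
  expect_equal(neighbor_counts(far), rep(1L, 2))

  pm <- random_profile_msa(8, 40, 0.4, q = 3, seed = 27)
  n <- neighbor_counts(pm$msa, 0.3)
  w <- sequence_weights(pm$msa, 0.3)
  expect_identical(1 / n, w$w)
})

test_that("PCA reproduces eigen-variances, ignores duplication, and
           separates constructed clusters", {
  pm <- random_profile_msa(10, 60, 0.7, q = 3, seed = 29)
  basis <- pca_fit(pm$msa, k = 3)
  proj <- pca_project(pm$msa, basis)
  expect_equal(apply(proj, 2, stats::var), basis$sdev[1:3]^2,
               ignore_attr = TRUE)
  expect_true(all(diff(basis$var_explained) <= 1e-12))
  expect_lte(sum(basis$var_explained), 1 + 1e-12)

  dup <- msa_rows(pm$msa, rep(seq_len(60), each = 2))
  basis2 <- pca_fit(dup, k = 2)
  # directions equal up to sign
  dots <- unname(abs(colSums(basis$components[, 1:2] * basis2$components)))
  expect_equal(dots, c(1, 1), tolerance = 1e-8)

  # two well-separated clusters: first PC separates them (silhouette > 0.5)
  cl1 <- matrix(1L, 30, 12); cl2 <- matrix(2L, 30, 12)
  set.seed(33)
  flip <- function(M) { idx <- cbind(sample(30, 30, TRUE),
                                     sample(12, 30, TRUE))
                        M[idx] <- 3L - M[idx]; M }
  two <- new_msa(rbind(flip(cl1), flip(cl2)), alphabet = ab2)
  pc1 <- pca_project(two, pca_fit(two, k = 1))[, 1]
  lab <- rep(1:2, each = 30)
  sil <- vapply(seq_along(pc1), function(i) {
    d <- abs(pc1 - pc1[i])
    a <- mean(d[lab == lab[i] & seq_along(pc1) != i])
    b <- mean(d[lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
})

test_that("rank-deficient requests reduce k with a warning", {
  tiny <- new_msa(rbind(c(1L, 1L), c(2L, 2L), c(1L, 2L)), alphabet = ab2)
  expect_warning(basis <- pca_fit(tiny, k = 4), "reduced")
  expect_lte(ncol(basis$components), 2)
})

test_that("nearest-neighbor score transfer is exact and permutation
           invariant", {
  nat <- random_profile_msa(12, 30, 1, q = 4, seed = 31)$msa
  scores <- stats::rnorm(30)
  gen <- msa_rows(nat, c(4, 9, 20))
  expect_equal(transfer_score_nn(gen, nat, scores), scores[c(4, 9, 20)])

  perm <- sample(30)
  expect_equal(transfer_score_nn(gen, msa_rows(nat, perm), scores[perm]),
               transfer_score_nn(gen, nat, scores))
  expect_error(transfer_score_nn(gen, nat, scores[1:5]), "one entry per")
})

test_that("DMS scores are additive with explicit missing-mutation policy", {
  ref <- "ACDEF"
  tab <- dms_table(ref, data.frame(position = c(2, 4), wt = c("C", "E"),
                                   mut = c("W", "K"),
                                   effect = c(-0.7, 0.3)))
  expect_equal(dms_score(ref, tab), list(score = 0, n_missing = 0L))
  expect_equal(dms_score("AWDEF", tab)$score, -0.7)
  # one tabulated (+0.3), one absent
  r2 <- dms_score("GCDKF", tab)
  expect_equal(r2$score, 0.3)
  expect_equal(r2$n_missing, 1L)
  # additivity when both are tabulated
  both <- dms_score("AWDKF", tab)
  expect_equal(both$score, -0.7 + 0.3)
  # gap at a differing position counts as missing even if never tabulated
  g <- dms_score("A-DEF", tab)
  expect_equal(g$score, 0)
  expect_equal(g$n_missing, 1L)
  expect_error(dms_score("ACD", tab), "length")
})

test_that("DMS tables round-trip through TSV and validate wt symbols", {
  ref <- "ACDEF"
  df <- data.frame(position = c(1, 3), wt = c("A", "D"), mut = c("V", "Y"),
                   effect = c(1.5, -2))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  tab <- read_dms_table(f, ref)
  expect_equal(dms_score("VCDEF", tab)$score, 1.5)
  bad <- df; bad$wt <- c("C", "D")
  expect_error(dms_table(ref, bad), "disagrees")
})
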