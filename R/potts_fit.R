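#' Configuration for the Boltzmann-machine fitter
#'
#' @param lambda L2 regularization strength on all parameters (default
#'   `1e-2`, the usual order of magnitude for deep alignments; use smaller
#'   values only with plenty of data).
#' @param learning_rate Gradient step size on the moment mismatch.
#' @param max_sweeps Maximum number of parameter updates.
#' @param n_samples Persistent chains used to estimate model moments when
#'   sampling is needed.
#' @param steps_per_sweep Metropolis steps applied to the persistent chains
#'   between parameter updates; default `max(20, 2*L*q)`.
#' @param tol Convergence tolerance on the maximum absolute one/two-body
#'   moment error.
#' @param moments `"auto"` uses exact enumeration when `q^L <= 4096` and
#'   Metropolis sampling otherwise; `"exact"` / `"mcmc"` force a choice.
#' @param gauge Apply the zero-sum gauge to the returned parameters (the
#'   fitted distribution is unchanged; see [zero_sum_gauge()]).
#' @param seed Integer seed.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(lambda = 1e-2, learning_rate = 0.1, max_sweeps = 500L,
                       n_samples = 2000L, steps_per_sweep = NULL, tol = 1e-2,
                       moments = c("auto", "exact", "mcmc"), gauge = TRUE,
                       seed = 1L) {
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(lambda = lambda, learning_rate = learning_rate,
                 max_sweeps = as.integer(max_sweeps),
                 n_samples = as.integer(n_samples),
                 steps_per_sweep = steps_per_sweep, tol = tol,
                 moments = match.arg(moments), gauge = isTRUE(gauge),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Fit a Potts model by Boltzmann-machine moment matching
#'
#' Iteratively updates fields and couplings along the mismatch between the
#' MSA's empirical one- and two-body frequencies and the current model's,
#' with an L2 penalty `lambda` on every parameter:
#' `h <- h + lr * (f1_data - f1_model - lambda * h)` and likewise for the
#' couplings of each site pair. Model moments come from exact enumeration on
#' small state spaces and otherwise from persistent Metropolis chains (a
#' persistent contrastive-divergence scheme). This is a minimal fitter in
#' the bmDCA family, not a port of any particular implementation.
#'
#' @param msa An [new_msa()] with `M >= 2` rows.
#' @param config A [fit_config()].
#' @return A [potts_model()] with attribute `"fit"`: list with `converged`,
#'   `sweeps`, `moment_error` (trace of the max absolute moment error per
#'   sweep), and `lambda`. A warning is issued when `max_sweeps` is reached
#'   before `tol`; the best-so-far parameters are returned.
#' @export
fit_boltzmann_machine <- function(msa, config = fit_config()) {
  if (msa_depth(msa) < 2L) stop("need at least 2 sequences to fit")
  L <- msa_length(msa); q <- msa$alphabet$q
  f1d <- msa_freq1(msa$data, L, q)
  f2d <- msa_freq2(msa$data, L, q)
  use_exact <- switch(config$moments,
                      exact = TRUE, mcmc = FALSE,
                      auto = q^L <= 4096)
  k <- if (is.null(config$steps_per_sweep)) max(20L, 2L * L * q)
       else as.integer(config$steps_per_sweep)
  h <- matrix(0, L, q)
  e <- array(0, c(L, L, q, q))
  chains <- NULL
  if (!use_exact) {
    chains <- with_seed(derive_seed(config$seed, "pcd-init"), {
      idx <- sample.int(msa_depth(msa), config$n_samples, replace = TRUE)
      msa$data[idx, , drop = FALSE]
    })
  }
  lr <- config$learning_rate; lam <- config$lambda
  errs <- numeric(0)
  best <- list(err = Inf, h = h, e = e)
  model <- potts_model(h, e, alphabet = msa$alphabet)
  for (sweep in seq_len(config$max_sweeps)) {
    if (use_exact) {
      mm <- exact_moments(model)
    } else {
      cfg <- sampling_config(n_steps = k, n_chains = nrow(chains),
                             init = "from_msa",
                             init_msa = new_msa(chains,
                                                alphabet = msa$alphabet),
                             seed = derive_seed(config$seed,
                                                paste0("pcd", sweep)))
      smp <- metropolis_sample(model, cfg)
      chains <- smp$data
      mm <- list(f1 = msa_freq1(chains, L, q), f2 = msa_freq2(chains, L, q))
    }
    err <- max(abs(mm$f1 - f1d))
    if (L >= 2L) err <- max(err, max(abs(mm$f2 - f2d)))
    errs <- c(errs, err)
    if (err < best$err) best <- list(err = err, h = h, e = e)
    if (err < config$tol) break
    h <- h + lr * (f1d - mm$f1 - lam * h)
    if (L >= 2L) {
      for (i in seq_len(L - 1L)) for (j in seq.int(i + 1L, L)) {
        g <- f2d[i, j, , ] - mm$f2[i, j, , ] - lam * e[i, j, , ]
        e[i, j, , ] <- e[i, j, , ] + lr * g
        e[j, i, , ] <- t(e[i, j, , ])
      }
    }
    model <- potts_model(h, e, alphabet = msa$alphabet)
  }
  converged <- length(errs) > 0 && min(errs) < config$tol
  if (!converged) {
    warning("fitter did not reach tol = ", config$tol, " within ",
            config$max_sweeps, " sweeps (best moment error ",
            signif(best$err, 3), "); returning best-so-far parameters")
    model <- potts_model(best$h, best$e, alphabet = msa$alphabet)
  }
  if (config$gauge) model <- zero_sum_gauge(model)
  attr(model, "fit") <- list(converged = converged, sweeps = length(errs),
                             moment_error = errs, lambda = lam)
  model
}

# Empirical one-body frequencies, L x q.
msa_freq1 <- function(data, L, q) {
  t(apply(data, 2L, tabulate, nbins = q)) / nrow(data)
}

# Empirical two-body frequencies, L x L x q x q (i < j filled symmetrically).
msa_freq2 <- function(data, L, q) {
  f2 <- array(0, c(L, L, q, q))
  if (L < 2L) return(f2)
  M <- nrow(data)
  for (i in seq_len(L - 1L)) for (j in seq.int(i + 1L, L)) {
    tab <- tabulate((data[, j] - 1L) * q + data[, i], nbins = q * q)
    f2[i, j, , ] <- matrix(tab, q, q) / M
    f2[j, i, , ] <- t(f2[i, j, , ])
  }
  f2
}

# Exact model moments by enumeration.
exact_moments <- function(model) {
  d <- exact_distribution(model)
  L <- model$L; q <- model$q
  f1 <- matrix(0, L, q)
  for (i in seq_len(L))
    f1[i, ] <- vapply(seq_len(q),
                      function(a) sum(d$prob[d$states[, i] == a]), 0)
  f2 <- array(0, c(L, L, q, q))
  if (L >= 2L) for (i in seq_len(L - 1L)) for (j in seq.int(i + 1L, L)) {
    for (a in seq_len(q)) for (b in seq_len(q))
      f2[i, j, a, b] <- sum(d$prob[d$states[, i] == a & d$states[, j] == b])
    f2[j, i, , ] <- t(f2[i, j, , ])
  }
  list(f1 = f1, f2 = f2)
}

#' Apply the zero-sum gauge to a Potts model
#'
#' Re-parameterizes fields and couplings so that every coupling block has
#' zero row and column means and every field has zero mean, without changing
#' the Boltzmann distribution (the Hamiltonian shifts by a constant). Used
#' for reporting fitted parameters comparably across runs.
#'
#' @param model A [potts_model()].
#' @return An equivalent [potts_model()] in the zero-sum gauge.
#' @export
zero_sum_gauge <- function(model) {
  L <- model$L; q <- model$q
  h <- model$h; e <- model$e
  if (L >= 2L) for (i in seq_len(L - 1L)) for (j in seq.int(i + 1L, L)) {
    J <- e[i, j, , ]
    rm_ <- rowMeans(J); cm_ <- colMeans(J); mm_ <- mean(J)
    e[i, j, , ] <- J - outer(rm_, rep(1, q)) - outer(rep(1, q), cm_) + mm_
    e[j, i, , ] <- t(e[i, j, , ])
    h[i, ] <- h[i, ] + rm_ - mm_
    h[j, ] <- h[j, ] + cm_ - mm_
  }
  h <- h - rowMeans(h)
  potts_model(h, e, alphabet = model$alphabet)
}

#' Write / read a Potts model in the package's JSON schema
#'
#' The schema stores `L`, `q`, the alphabet string, the `L x q` field matrix
#' `h` (row-major list of rows), and the couplings as a list of
#' `{i, j, e}` entries for `i < j` with `e` a `q x q` matrix whose rows index
#' site `i`. Zero coupling blocks may be omitted.
#'
#' @param model A [potts_model()].
#' @param path Output / input file path.
#' @return `write_potts` returns `path` invisibly; `read_potts` returns a
#'   [potts_model()].
#' @export
write_potts <- function(model, path) {
  pairs <- list()
  if (model$L >= 2L) for (i in seq_len(model$L - 1L))
    for (j in seq.int(i + 1L, model$L)) {
      if (any(model$e[i, j, , ] != 0))
        pairs[[length(pairs) + 1L]] <-
          list(i = i, j = j, e = model$e[i, j, , ])
    }
  obj <- list(L = model$L, q = model$q,
              alphabet = paste(model$alphabet$symbols, collapse = ""),
              h = model$h, couplings = pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potts
#' @export
read_potts <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ab <- make_alphabet(strsplit(obj$alphabet, "")[[1]])
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r)
    as.numeric(unlist(r))))
  h <- as_mat(obj$h)
  e <- list()
  for (entry in obj$couplings)
    e[[paste0(entry$i, "_", entry$j)]] <- as_mat(entry$e)
  potts_model(h, if (length(e)) e else NULL, alphabet = ab)
}
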