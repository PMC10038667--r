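#' Configuration for the iterative masking procedure
#'
#' Defaults follow the regime in which the procedure is known to converge
#' while preserving family structure: masking probability `p = 0.1` and
#' `iterations = 200` for whole-MSA masking, so each cell is masked
#' `p * iterations = 20` times on average. For the first-row scopes far
#' fewer rounds are needed; `iterations = 20` is the usual choice there.
#'
#' @param p Masking probability in `[0, 1]`.
#' @param iterations Number of mask-fill rounds (`I >= 0`).
#' @param batch_depth Rows per model call when generating a full MSA.
#' @param selection `"greedy"` (argmax token, the sampling-temperature-zero
#'   limit) or `"softmax"` (token drawn from `softmax(logits / t_sel)`).
#' @param t_sel Softmax selection temperature (`> 0`); higher values promote
#'   originality at the cost of sequence quality.
#' @param scope `"whole_msa"` masks every cell; the `"first_row_*"` scopes
#'   mask only row 1, the remaining rows acting as context (fixed, or
#'   resampled from a pool every iteration).
#' @param seed Integer seed; all per-iteration randomness is derived from it.
#' @return A list of class `"generation_config"`.
#' @export
generation_config <- function(p = 0.1, iterations = 200L, batch_depth = 600L,
                              selection = c("greedy", "softmax"), t_sel = 1,
                              scope = c("whole_msa", "first_row_fixed_context",
                                        "first_row_variable_context"),
                              seed = 1L) {
  selection <- match.arg(selection)
  scope <- match.arg(scope)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (iterations < 0) stop("iterations must be >= 0")
  if (selection == "softmax" && t_sel <= 0)
    stop("t_sel must be > 0 for softmax selection")
  structure(list(p = p, iterations = as.integer(iterations),
                 batch_depth = as.integer(batch_depth),
                 selection = selection, t_sel = t_sel, scope = scope,
                 seed = as.integer(seed)),
            class = "generation_config")
}

#' Mask MSA cells at random
#'
#' Each eligible cell is masked independently with probability `p`
#' (eligible means every cell for `"whole_msa"` scope, row-1 cells for the
#' first-row scopes). Masked cells carry the reserved mask value
#' (`NA`) in the returned MSA copy; gaps are maskable like any residue.
#'
#' @param msa An [new_msa()] object.
#' @param p Masking probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param scope See [generation_config()].
#' @return A list with `masked` (the MSA with `NA` at masked cells) and
#'   `mask` (an `n x 2` integer matrix of (row, column) pairs).
#' @export
mask_msa <- function(msa, p, seed = 1L, scope = "whole_msa") {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  M <- msa_depth(msa); L <- msa_length(msa)
  rows_elig <- if (scope == "whole_msa") seq_len(M) else 1L
  hit <- with_seed(seed,
                   matrix(stats::runif(length(rows_elig) * L) < p,
                          length(rows_elig), L))
  idx <- which(hit, arr.ind = TRUE)
  mask <- cbind(row = rows_elig[idx[, 1L]], col = idx[, 2L])
  masked <- msa
  if (nrow(mask)) masked$data[mask] <- NA_integer_
  list(masked = masked, mask = mask)
}

# Extract the n_mask x q logit matrix for the masked cells.
mask_logits <- function(logits, mask, q) {
  n <- nrow(mask)
  lg <- matrix(0, n, q)
  for (a in seq_len(q)) lg[, a] <- logits[cbind(mask[, 1L], mask[, 2L], a)]
  if (any(!is.finite(lg)))
    stop("model contract violation: non-finite logits at masked cells")
  lg
}

#' Fill masked cells from model logits
#'
#' Greedy selection sets each masked cell to the argmax symbol (ties broken
#' toward the lowest symbol index); softmax selection draws the symbol from
#' `softmax(logits / t_sel)`. Unmasked cells are untouched and the mask
#' value never appears in the output.
#'
#' @param masked MSA with `NA` at masked cells (from [mask_msa()]).
#' @param mask The `(row, column)` mask matrix.
#' @param logits An `M x L x q` array from a masked-sequence model.
#' @param selection `"greedy"` or `"softmax"`.
#' @param t_sel Softmax temperature.
#' @param seed Integer seed (used by softmax selection).
#' @return An [new_msa()] with every masked cell filled.
#' @export
fill_masked <- function(masked, mask, logits,
                        selection = c("greedy", "softmax"), t_sel = 1,
                        seed = 1L) {
  selection <- match.arg(selection)
  q <- masked$alphabet$q
  out <- masked$data
  if (nrow(mask)) {
    if (!identical(dim(logits),
                   as.integer(c(nrow(out), ncol(out), q))))
      stop("model contract violation: logits must be M x L x q")
    lg <- mask_logits(logits, mask, q)
    if (selection == "greedy") {
      sym <- max.col(lg, ties.method = "first")
    } else {
      z <- lg / t_sel
      z <- z - apply(z, 1L, max)
      P <- exp(z); P <- P / rowSums(P)
      cs <- t(apply(P, 1L, cumsum))
      u <- with_seed(seed, stats::runif(nrow(mask)))
      sym <- max.col(cs >= u, ties.method = "first")
    }
    out[mask] <- sym
  }
  new_msa(out, masked$ids, masked$alphabet)
}

#' The iterative masking procedure
#'
#' Repeats, for `iterations` rounds: (1) mask each eligible cell with
#' probability `p` (fresh Bernoulli draws every round), (2) evaluate the
#' masked-sequence model once on the whole masked alignment, (3) fill all
#' masked cells simultaneously from the returned logits. The alignment's
#' shape and column structure are preserved throughout. Under the
#' `"first_row_variable_context"` scope, rows 2..M are resampled from
#' `context_pool` at every round.
#'
#' @param msa Input [new_msa()] (a single batch: depth at most
#'   `config$batch_depth`).
#' @param model A `"masked_sequence_model"` (see [new_mlm()]).
#' @param config A [generation_config()].
#' @param context_pool An [new_msa()] supplying context rows for the
#'   variable-context scope.
#' @param record If `TRUE`, attach attributes `"trace"` (the focal first row
#'   after every round, an `iterations x L` matrix) and `"mask_counts"`
#'   (times each cell was masked).
#' @return An [new_msa()] of identical dimensions.
#' @export
iterative_masking <- function(msa, model, config = generation_config(),
                              context_pool = NULL, record = FALSE) {
  M <- msa_depth(msa); L <- msa_length(msa); q <- msa$alphabet$q
  if (M > config$batch_depth)
    stop("MSA depth exceeds batch_depth; use generate_synthetic_msa()")
  if (config$scope == "first_row_variable_context" && is.null(context_pool))
    stop("variable-context scope requires a context_pool")
  cur <- msa
  trace <- if (record) matrix(0L, config$iterations, L) else NULL
  counts <- if (record) matrix(0L, M, L) else NULL
  for (t in seq_len(config$iterations)) {
    if (config$scope == "first_row_variable_context") {
      idx <- with_seed(derive_seed(config$seed, paste0("ctx", t)),
                       sample.int(msa_depth(context_pool), M - 1L,
                                  replace = msa_depth(context_pool) < M - 1L))
      cur$data[-1L, ] <- context_pool$data[idx, , drop = FALSE]
    }
    mk <- mask_msa(cur, config$p, seed = derive_seed(config$seed,
                                                     paste0("mask", t)),
                   scope = config$scope)
    if (nrow(mk$mask)) {
      logits <- model(mk$masked, mk$mask)
      if (!identical(dim(logits), as.integer(c(M, L, q))))
        stop("model contract violation: logits must be M x L x q")
      cur <- fill_masked(mk$masked, mk$mask, logits,
                         selection = config$selection, t_sel = config$t_sel,
                         seed = derive_seed(config$seed, paste0("fill", t)))
      if (record) counts[mk$mask] <- counts[mk$mask] + 1L
    }
    if (record) trace[t, ] <- cur$data[1L, ]
  }
  if (record) {
    attr(cur, "trace") <- trace
    attr(cur, "mask_counts") <- counts
  }
  cur
}

#' Generate a synthetic MSA of the same depth as a natural one
#'
#' Partitions the natural MSA into batches of at most `batch_depth` rows
#' (uniformly at random, without replacement), runs the iterative masking
#' procedure independently on each batch, and concatenates the per-batch
#' outputs in plan order. The result has exactly the natural depth.
#'
#' @param natural The natural [new_msa()].
#' @param model A `"masked_sequence_model"`.
#' @param config A [generation_config()].
#' @return An [new_msa()] of the same depth and length as `natural`, with
#'   attribute `"plan"` (the [plan_batches()] used).
#' @export
generate_synthetic_msa <- function(natural, model,
                                   config = generation_config()) {
  plan <- plan_batches(natural, config$batch_depth,
                       seed = derive_seed(config$seed, "batches"))
  pieces <- vector("list", length(plan$batches))
  for (b in seq_along(plan$batches)) {
    sub <- msa_rows(natural, plan$batches[[b]])
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("batch", b))
    pieces[[b]] <- iterative_masking(sub, model, cfg)
  }
  out <- new_msa(do.call(rbind, lapply(pieces, function(p) p$data)),
                 ids = unlist(lapply(pieces, function(p) p$ids)),
                 alphabet = natural$alphabet)
  attr(out, "plan") <- plan
  out
}

#' Pseudolikelihood loss of a masked-sequence model on an MSA
#'
#' The masked-language-modeling objective: minus the sum, over masked cells,
#' of the log softmax-normalized model probability of the true symbol.
#' Always non-negative; zero only if the model puts probability one on every
#' true symbol.
#'
#' @param model A `"masked_sequence_model"`.
#' @param msa The unmasked [new_msa()] holding the true symbols.
#' @param mask An `n x 2` (row, column) matrix of cells to mask; must be
#'   non-empty.
#' @return The scalar loss (natural log).
#' @export
pseudolikelihood_loss <- function(model, msa, mask) {
  if (is.null(dim(mask)) || nrow(mask) == 0L)
    stop("mask must contain at least one cell")
  masked <- msa
  masked$data[mask] <- NA_integer_
  logits <- model(masked, mask)
  lg <- mask_logits(logits, mask, msa$alphabet$q)
  truth <- msa$data[mask]
  mx <- apply(lg, 1L, max)
  logp <- lg[cbind(seq_len(nrow(mask)), truth)] - mx -
    log(rowSums(exp(lg - mx)))
  -sum(logp)
}
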