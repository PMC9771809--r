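# Prediction-set combination: weighted averaging and genetic-algorithm
# subset selection.

# A prediction set is a named list of matrices (scored positions x channels,
# with channel column names), one matrix per construct.

check_aligned_sets <- function(members) {
  if (!length(members)) stop("no prediction sets supplied", call. = FALSE)
  ref <- members[[1]]
  ids <- names(ref)
  for (m in members[-1]) {
    if (!identical(names(m), ids)) {
      stop("prediction sets have mismatched construct ids", call. = FALSE)
    }
    for (id in ids) {
      if (!identical(dim(m[[id]]), dim(ref[[id]])) ||
          !identical(colnames(m[[id]]), colnames(ref[[id]]))) {
        stop(sprintf("prediction sets misaligned on construct '%s'", id),
             call. = FALSE)
      }
    }
  }
  invisible(ids)
}

#' Weighted average of aligned prediction sets
#'
#' @param members List of prediction sets (each a named list of
#'   positions-by-channels matrices), aligned on ids, dimensions and
#'   channels.
#' @param weights Non-negative weights, one per member (default uniform);
#'   normalized to sum to 1.
#' @return A prediction set of the same shape.
#' @export
average_predictions <- function(members, weights = NULL) {
  ids <- check_aligned_sets(members)
  K <- length(members)
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative, one per member, not all zero",
         call. = FALSE)
  }
  w <- weights / sum(weights)
  out <- lapply(ids, function(id) {
    acc <- members[[1]][[id]] * w[1]
    if (K > 1L) for (k in 2:K) acc <- acc + members[[k]][[id]] * w[k]
    acc
  })
  names(out) <- ids
  out
}

# Flatten a prediction set to one long numeric vector (channel-major blocks
# are tracked separately for per-channel RMSE).
flatten_set <- function(set) {
  ids <- names(set)
  ch <- colnames(set[[1]])
  vec <- unlist(lapply(set, as.numeric), use.names = FALSE)
  chan_idx <- unlist(lapply(set, function(m) {
    rep(seq_along(ch), each = nrow(m))
  }), use.names = FALSE)
  list(values = vec, channel = chan_idx, n_channels = length(ch))
}

# MCRMSE from flattened vectors: mean over channels of pooled RMSE.
flat_mcrmse <- function(pred_vec, truth_flat) {
  res2 <- (pred_vec - truth_flat$values)^2
  mean(vapply(seq_len(truth_flat$n_channels), function(j) {
    sqrt(mean(res2[truth_flat$channel == j]))
  }, 0))
}

#' Genetic-algorithm selection of a small prediction ensemble
#'
#' Searches over subsets of at most `max_members` candidate prediction sets
#' and their mixing weights, minimizing the MCRMSE against `truth` on the
#' optimization split. Chromosomes encode a membership mask plus positive
#' weights (renormalized over the active members); search uses tournament
#' selection, uniform crossover, bit-flip/weight-jitter mutation and
#' elitism. The initial population contains the best single candidate, and
#' elites are carried unchanged, so the returned ensemble never scores
#' worse than the best single candidate on the optimization split.
#'
#' The optimization score is what the GA saw; evaluate the returned spec on
#' a held-out split (via [ensemble_predictions()] and [mcrmse()]) to detect
#' overfitting of the ensemble search itself.
#'
#' @param candidates Named list of prediction sets.
#' @param truth Prediction-set-shaped list of measured values, aligned with
#'   every candidate.
#' @param max_members Maximum ensemble size (default 10).
#' @param generations,pop_size,mutation_rate,elitism GA hyperparameters
#'   (defaults 200, 64, 0.05, 2).
#' @param uniform_weights Restrict the search to uniform weights over the
#'   selected subset.
#' @param seed RNG seed; the search is fully reproducible.
#' @return An object of class `ensemble_spec`: list with `member_ids`,
#'   `weights` (named, summing to 1), `objective_score` (optimization-split
#'   MCRMSE), and `history` (best score per generation).
#' @export
ga_select <- function(candidates, truth, max_members = 10L,
                      generations = 200L, pop_size = 64L,
                      mutation_rate = 0.05, elitism = 2L,
                      uniform_weights = FALSE, seed = 1L) {
  if (!length(candidates)) stop("no candidate prediction sets", call. = FALSE)
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("model_", seq_along(candidates))
  }
  check_aligned_sets(c(list(truth), unname(candidates)))
  K <- length(candidates)
  max_members <- min(max_members, K)

  truth_flat <- flatten_set(truth)
  P <- vapply(candidates, function(s) flatten_set(s)$values,
              numeric(length(truth_flat$values)))   # n_flat x K

  eval_chrom <- function(mask, w) {
    w_act <- if (uniform_weights) rep(1, sum(mask)) else w[mask]
    w_act <- w_act / sum(w_act)
    pred <- drop(P[, mask, drop = FALSE] %*% w_act)
    flat_mcrmse(pred, truth_flat)
  }

  repair_mask <- function(mask) {
    on <- which(mask)
    if (length(on) > max_members) {
      mask[sample(on, length(on) - max_members)] <- FALSE
    } else if (!any(mask)) {
      mask[sample.int(K, 1L)] <- TRUE
    }
    mask
  }

  new_chrom <- function(mask, w) list(mask = mask, w = w)

  with_seed(seed, {
    single_scores <- vapply(seq_len(K), function(k) {
      eval_chrom(seq_len(K) == k, rep(1, K))
    }, 0)
    best_single <- which.min(single_scores)

    pop <- vector("list", pop_size)
    pop[[1]] <- new_chrom(seq_len(K) == best_single, rep(1, K))
    for (i in seq_len(pop_size)[-1]) {
      m <- rep(FALSE, K)
      m[sample.int(K, sample.int(max_members, 1L))] <- TRUE
      pop[[i]] <- new_chrom(m, stats::runif(K, 0.2, 1))
    }
    scores <- vapply(pop, function(c) eval_chrom(c$mask, c$w), 0)
    history <- numeric(generations)
    best_score <- min(scores)

    for (g in seq_len(generations)) {
      ord <- order(scores)
      elite <- pop[ord[seq_len(elitism)]]
      offspring <- vector("list", pop_size - elitism)
      for (i in seq_along(offspring)) {
        pick <- function() {
          cand <- sample.int(pop_size, 3L)
          pop[[cand[which.min(scores[cand])]]]
        }
        pa <- pick(); pb <- pick()
        take <- stats::runif(K) < 0.5
        mask <- ifelse(take, pa$mask, pb$mask)
        w <- ifelse(take, pa$w, pb$w)
        flip <- stats::runif(K) < mutation_rate
        mask[flip] <- !mask[flip]
        w <- w * exp(stats::rnorm(K, 0, 0.2) *
                       (stats::runif(K) < mutation_rate))
        offspring[[i]] <- new_chrom(repair_mask(mask), pmax(w, 1e-8))
      }
      pop <- c(elite, offspring)
      scores <- vapply(pop, function(c) eval_chrom(c$mask, c$w), 0)
      gen_best <- min(scores)
      # elitism invariant: the best score can never regress, and never
      # exceeds the best single candidate seeded into the population
      stopifnot(gen_best <= best_score + 1e-12,
                gen_best <= single_scores[best_single] + 1e-12)
      best_score <- gen_best
      history[g] <- best_score
    }

    # tie-break among optimal chromosomes: fewer members, then lexical ids
    opt <- which(scores <= best_score + 1e-12)
    sizes <- vapply(pop[opt], function(c) sum(c$mask), 0L)
    opt <- opt[order(sizes, vapply(pop[opt], function(c) {
      paste(sort(names(candidates)[c$mask]), collapse = ",")
    }, ""))]
    champ <- pop[[opt[1]]]
    w_act <- if (uniform_weights) rep(1, sum(champ$mask)) else
      champ$w[champ$mask]
    w_act <- w_act / sum(w_act)
    structure(list(member_ids = names(candidates)[champ$mask],
                   weights = stats::setNames(w_act,
                                             names(candidates)[champ$mask]),
                   objective_score = eval_chrom(champ$mask, champ$w),
                   best_single = names(candidates)[best_single],
                   best_single_score = single_scores[best_single],
                   history = history),
              class = "ensemble_spec")
  })
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("ensemble of %d model(s), optimization MCRMSE %.5f (best single: %s, %.5f)\n",
              length(x$member_ids), x$objective_score,
              x$best_single, x$best_single_score))
  for (id in x$member_ids) {
    cat(sprintf("  %-20s weight %.4f\n", id, x$weights[id]))
  }
  invisible(x)
}

#' Combine candidate prediction sets according to an ensemble spec
#'
#' @param spec An `ensemble_spec` from [ga_select()].
#' @param candidates The named candidate list the spec refers to.
#' @return The ensembled prediction set.
#' @export
ensemble_predictions <- function(spec, candidates) {
  missing <- setdiff(spec$member_ids, names(candidates))
  if (length(missing)) {
    stop("candidates missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  average_predictions(candidates[spec$member_ids], unname(spec$weights))
}
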