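# The DegScore model family: windowed linear (ridge / minimum-norm least
# squares) and gradient-boosted per-nucleotide degradation predictors.

#' Fit a windowed degradation model to per-nucleotide measurements
#'
#' Fits a predictor of per-nucleotide degradation (or SHAPE reactivity) from
#' one-hot windowed sequence and loop-type context. The linear variant models
#' the measurement at position i as
#' \deqn{Y_i = \sum_{k=-w}^{w} \sum_{n \in \{A,C,G,U\}} \beta_{k,n} I_{i+k,n}
#'       + \sum_{k=-w}^{w} \sum_{s \in \{H,E,I,M,B,S\}} \beta_{k,s} I_{i+k,s}
#'       + \beta_0,}
#' estimated by least squares with an L2 penalty `lambda` on the slope
#' coefficients (the intercept is never penalized). With `lambda = 0` and a
#' rank-deficient design (which is structural here: within every offset the
#' sequence indicators and the loop indicators both sum to the same
#' in-bounds flag) the minimum-norm least-squares solution is returned with
#' a warning. `method = "xgb"` trains a gradient-boosted tree regressor on
#' the same feature columns.
#'
#' Only the scored 5' prefix of each construct (`seq_scored` positions)
#' enters the fit.
#'
#' @param records List of RNA records (see [rna_record()]) carrying the
#'   target channel on their scored positions.
#' @param channel Measurement channel to fit, e.g. `"deg_Mg_pH10"` or
#'   `"reactivity"`.
#' @param window Window half-width w (default 12; 251 parameters).
#' @param lambda Ridge penalty on slopes (default 0.1; `0` requests plain
#'   least squares, minimum-norm when singular).
#' @param method `"ridge"` (linear) or `"xgb"` (gradient-boosted trees).
#' @param merge_x_into_e Encode exterior-loop `X` as `E` (default `TRUE`).
#' @param xgb_params Hyperparameters for `method = "xgb"`: a list with
#'   elements `nrounds`, `max_depth`, `eta` (defaults 200, 6, 0.1).
#' @param seed RNG seed used by the boosted variant.
#' @return An object of class `degscore` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot` methods.
#' @examples
#' recs <- make_dataset(synthetic_config(n_constructs = 8, length = 40,
#'                                       scored_length = 30, window = 2))
#' fit <- degscore(recs, channel = "deg_Mg_pH10", window = 2)
#' fit
#' head(predict(fit, recs[[1]]))
#' @export
degscore <- function(records, channel = "deg_Mg_pH10", window = 12L,
                     lambda = 0.1, method = c("ridge", "xgb"),
                     merge_x_into_e = TRUE,
                     xgb_params = list(nrounds = 200L, max_depth = 6L,
                                       eta = 0.1),
                     seed = 1L) {
  method <- match.arg(method)
  if (inherits(records, "rna_record")) records <- list(records)
  if (!length(records)) stop("no records to fit on", call. = FALSE)
  fz <- window_featurizer(window, merge_x_into_e)
  xy <- assemble_design(records, channel, fz)
  if (!nrow(xy$X)) stop("no scored positions in the dataset", call. = FALSE)
  if (anyNA(xy$y)) {
    stop(sprintf("channel '%s' contains missing values", channel),
         call. = FALSE)
  }

  obj <- list(channel = channel, featurizer = fz, method = method,
              n_obs = nrow(xy$X), n_records = length(records),
              call = match.call())
  if (method == "ridge") {
    theta <- solve_ridge(xy$X, xy$y, lambda)
    obj$lambda <- lambda
    obj$intercept <- unname(theta[1])
    obj$coefficients <- stats::setNames(theta[-1], colnames(xy$X))
    fit_vals <- drop(xy$X %*% theta[-1]) + theta[1]
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stop("the xgboost package is required for method = 'xgb'",
           call. = FALSE)
    }
    booster <- with_seed(seed, xgboost::xgboost(
      x = xy$X, y = xy$y,
      nrounds = xgb_params$nrounds %||% 200L,
      max_depth = xgb_params$max_depth %||% 6L,
      learning_rate = xgb_params$eta %||% 0.1,
      objective = "reg:squarederror",
      nthreads = 1L, verbosity = 0L, seed = seed))
    obj$booster <- booster
    obj$xgb_params <- xgb_params
    obj$seed <- seed
    fit_vals <- stats::predict(booster, xy$X)
  }
  obj$fitted.values <- fit_vals
  obj$residuals <- xy$y - fit_vals
  obj$training_rmse <- sqrt(mean(obj$residuals^2))
  class(obj) <- "degscore"
  obj
}

# Stack scored-position feature rows and targets across records.
assemble_design <- function(records, channel, fz) {
  Xs <- vector("list", length(records))
  ys <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r[[channel]])) {
      stop(sprintf("record '%s' lacks channel '%s'",
                   r$id %||% i, channel), call. = FALSE)
    }
    loops <- r$predicted_loop_type %||% annotate_loop_types(r$structure)
    M <- featurize(r$sequence, loops, fz)
    scored <- seq_len(r$seq_scored %||% length(r[[channel]]))
    Xs[[i]] <- M[scored, , drop = FALSE]
    ys[[i]] <- as.numeric(r[[channel]])[scored]
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

# Ridge / minimum-norm least squares with unpenalized intercept.
solve_ridge <- function(X, y, lambda) {
  A <- cbind(`(Intercept)` = 1, X)
  p <- ncol(A)
  if (lambda > 0) {
    G <- crossprod(A) + diag(c(0, rep(lambda, p - 1L)))
    drop(solve(G, crossprod(A, y)))
  } else {
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
    r <- sum(sv$d > tol)
    if (r < p) {
      warning(sprintf(
        "design is rank deficient (rank %d < %d columns); returning the minimum-norm least-squares solution",
        r, p), call. = FALSE)
    }
    idx <- seq_len(r)
    drop(sv$v[, idx, drop = FALSE] %*%
           (crossprod(sv$u[, idx, drop = FALSE], y) / sv$d[idx]))
  }
}

#' Predict per-nucleotide degradation from a fitted model
#'
#' Predictions are computed for every position of each supplied construct
#' (full length, not just the scored prefix), so downstream whole-molecule
#' aggregation can account for interactions outside the probed window.
#'
#' @param object A fitted `degscore` model.
#' @param newdata A single RNA record, a list of records, or a list with
#'   elements `sequence` and `structure` (or `predicted_loop_type`).
#' @param ... Unused.
#' @return A numeric vector for a single construct, otherwise a named list
#'   of numeric vectors.
#' @export
predict.degscore <- function(object, newdata, ...) {
  single <- inherits(newdata, "rna_record") ||
    (is.list(newdata) && !is.null(newdata$sequence))
  recs <- if (single) list(newdata) else newdata
  out <- lapply(recs, function(r) {
    loops <- r$predicted_loop_type %||% annotate_loop_types(r$structure)
    M <- featurize(r$sequence, loops, object$featurizer)
    predict_features(object, M)
  })
  names(out) <- vapply(recs, function(r) r$id %||% "", "")
  if (single) out[[1]] else out
}

# Predict from an already-built feature matrix.
predict_features <- function(object, M) {
  if (object$method == "ridge") {
    if (ncol(M) != length(object$coefficients)) {
      stop("feature matrix does not match the model's featurizer",
           call. = FALSE)
    }
    drop(M %*% object$coefficients) + object$intercept
  } else {
    stats::predict(object$booster, M)
  }
}

#' @export
coef.degscore <- function(object, ...) {
  if (object$method != "ridge") {
    stop("coefficients are only defined for the linear model", call. = FALSE)
  }
  c("(Intercept)" = unname(object$intercept), object$coefficients)
}

#' Coefficient table of a linear degradation model
#'
#' @param object A fitted linear `degscore` model.
#' @return Data frame with columns `offset`, `indicator`, `beta`.
#' @export
coef_table <- function(object) {
  stopifnot(inherits(object, "degscore"))
  if (object$method != "ridge") {
    stop("coefficients are only defined for the linear model", call. = FALSE)
  }
  parts <- strsplit(names(object$coefficients), ":", fixed = TRUE)
  data.frame(offset = as.integer(vapply(parts, `[`, "", 1L)),
             indicator = vapply(parts, `[`, "", 2L),
             beta = unname(object$coefficients))
}

#' @export
fitted.degscore <- function(object, ...) object$fitted.values

#' @export
residuals.degscore <- function(object, ...) object$residuals

#' @export
print.degscore <- function(x, ...) {
  cat(sprintf("DegScore %s model for channel '%s'\n",
              if (x$method == "ridge") "linear" else "gradient-boosted",
              x$channel))
  cat(sprintf("  window w = %d (%d parameters)%s\n",
              x$featurizer$window, count_parameters(x$featurizer$window),
              if (x$method == "ridge")
                sprintf(", lambda = %g", x$lambda) else ""))
  cat(sprintf("  fitted on %d scored positions from %d constructs; training RMSE %.4f\n",
              x$n_obs, x$n_records, x$training_rmse))
  invisible(x)
}

#' @export
summary.degscore <- function(object, ...) {
  out <- list(model = object)
  if (object$method == "ridge") {
    tab <- coef_table(object)
    out$top_coefficients <- tab[order(-abs(tab$beta)), ][1:min(10, nrow(tab)), ]
  }
  class(out) <- "summary.degscore"
  out
}

#' @export
print.summary.degscore <- function(x, ...) {
  print(x$model)
  if (!is.null(x$top_coefficients)) {
    cat("largest-magnitude coefficients:\n")
    print(x$top_coefficients, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the coefficient grid of a linear degradation model
#'
#' Displays the fitted coefficients as an offset-by-indicator heat map.
#'
#' @param x A fitted linear `degscore` model.
#' @param ... Passed to [graphics::image()].
#' @export
plot.degscore <- function(x, ...) {
  tab <- coef_table(x)
  fz <- x$featurizer
  inds <- c(fz$seq_alphabet, fz$struct_alphabet)
  offsets <- -fz$window:fz$window
  Z <- matrix(tab$beta, nrow = length(offsets), byrow = TRUE)
  graphics::image(x = offsets, y = seq_along(inds), z = Z,
                  xlab = "offset k", ylab = "", yaxt = "n",
                  main = sprintf("DegScore coefficients (%s)", x$channel), ...)
  graphics::axis(2, at = seq_along(inds), labels = inds, las = 1)
  invisible(x)
}
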