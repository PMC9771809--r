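# Scoring metrics: MCRMSE, signal-to-noise, within-error agreement,
# motif-level aggregation and rank correlation.

# Normalize measured/predicted inputs to a single matrix per channel by
# stacking constructs row-wise. Accepts a matrix (positions x channels) or a
# named list of such matrices.
stack_channels <- function(x, what = "input") {
  if (is.matrix(x)) x <- list(x)
  if (!length(x)) stop(sprintf("empty %s", what), call. = FALSE)
  cols <- colnames(x[[1]])
  if (is.null(cols)) stop(sprintf("%s matrices need channel column names", what),
                          call. = FALSE)
  for (m in x) {
    if (!is.matrix(m) || !identical(colnames(m), cols)) {
      stop(sprintf("%s matrices have inconsistent channels", what),
           call. = FALSE)
    }
  }
  do.call(rbind, x)
}

#' Mean column RMSE (MCRMSE) of a prediction set
#'
#' The competition metric for multi-channel per-nucleotide prediction: for
#' each scored channel, the root-mean-square error pooled over every scored
#' nucleotide of every construct in the dataset; the MCRMSE is the
#' arithmetic mean of the per-channel RMSEs.
#'
#' @param measured,predicted Matrices (scored positions x channels, with
#'   channel column names) or named lists of such matrices, one per
#'   construct, aligned between the two arguments.
#' @param mask Optional logical matrix/list of matrices marking scored
#'   entries (default: everything).
#' @param na_skip Drop positions where either side is `NA`/`NaN` instead of
#'   raising an error.
#' @return An object of class `score_report`: list with `per_channel_rmse`
#'   (named vector), `mcrmse` and `n_scored_nt`.
#' @examples
#' m <- cbind(reactivity = c(1, 2, 3), deg_Mg_pH10 = c(0, 1, 0))
#' mcrmse(m, m + 1)$mcrmse   # residuals uniformly 1 -> 1
#' @export
mcrmse <- function(measured, predicted, mask = NULL, na_skip = FALSE) {
  Y <- stack_channels(measured, "measured")
  P <- stack_channels(predicted, "predicted")
  if (!identical(dim(Y), dim(P))) {
    stop("measured and predicted shapes differ", call. = FALSE)
  }
  keep <- if (is.null(mask)) {
    matrix(TRUE, nrow(Y), ncol(Y))
  } else {
    stack_channels(mask, "mask") > 0
  }
  if (anyNA(Y[keep]) || anyNA(P[keep])) {
    if (!na_skip) {
      stop("missing values in scored entries (set na_skip = TRUE to drop them)",
           call. = FALSE)
    }
    keep <- keep & !is.na(Y) & !is.na(P)
  }
  rmse <- vapply(seq_len(ncol(Y)), function(j) {
    k <- keep[, j]
    if (!any(k)) stop(sprintf("channel '%s' has no scored positions",
                              colnames(Y)[j]), call. = FALSE)
    sqrt(mean((Y[k, j] - P[k, j])^2))
  }, 0)
  names(rmse) <- colnames(Y)
  structure(list(per_channel_rmse = rmse,
                 mcrmse = mean(rmse),
                 n_scored_nt = sum(keep)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("MCRMSE %.5f over %d channels (%d scored entries)\n",
              x$mcrmse, length(x$per_channel_rmse), x$n_scored_nt))
  for (ch in names(x$per_channel_rmse)) {
    cat(sprintf("  %-14s RMSE %.5f\n", ch, x$per_channel_rmse[ch]))
  }
  invisible(x)
}

#' Signal-to-noise ratio of a construct's measurements
#'
#' Mean over channels of the mean over positions of mu / sigma, where mu is
#' the measured value and sigma its estimated standard deviation.
#'
#' @param values Numeric vector or matrix (positions x channels) of means.
#' @param errors Matching vector/matrix of per-position standard deviations.
#' @param zero_sigma `"error"` (default) to fail on sigma <= 0, `"exclude"`
#'   to drop those positions from the mean.
#' @return The signal-to-noise ratio.
#' @export
sn_ratio <- function(values, errors, zero_sigma = c("error", "exclude")) {
  zero_sigma <- match.arg(zero_sigma)
  values <- as.matrix(values); errors <- as.matrix(errors)
  if (!identical(dim(values), dim(errors))) {
    stop("values and errors shapes differ", call. = FALSE)
  }
  bad <- errors <= 0
  if (any(bad)) {
    if (zero_sigma == "error") {
      stop("non-positive sigma encountered", call. = FALSE)
    }
    values[bad] <- NA
  }
  per_channel <- colMeans(values / errors, na.rm = TRUE)
  mean(per_channel)
}

#' Fraction of predictions within experimental error
#'
#' The fraction of positions where the absolute prediction error is strictly
#' smaller than the experimental uncertainty. If experimental errors are
#' Gaussian, an error-free predictor is expected to fall within one standard
#' deviation at about 68.3\% of positions, which bounds the achievable
#' agreement of any model.
#'
#' @param predicted,measured,error Aligned numeric vectors (or matrices).
#' @return The agreement fraction in `[0, 1]`.
#' @export
within_error_fraction <- function(predicted, measured, error) {
  if (length(predicted) != length(measured) ||
      length(measured) != length(error)) {
    stop("predicted, measured and error lengths differ", call. = FALSE)
  }
  if (any(error < 0)) stop("negative experimental errors", call. = FALSE)
  mean(abs(predicted - measured) < error)
}

#' Aggregate per-position values over secondary-structure motifs
#'
#' Pools values across constructs by structural context and reports the mean
#' and standard deviation per motif bin. Base bins are the bpRNA loop
#' classes; derived bins are `triloop` (hairpin loop of exactly 3 unpaired
#' nucleotides) and the split of internal-loop positions into
#' `internal_symmetric` / `internal_asymmetric` by side-length equality.
#'
#' @param values List of numeric vectors (one per construct); each may cover
#'   the full construct or just its scored prefix.
#' @param structures List (or vector) of dot-bracket strings or pair tables
#'   aligned with `values`.
#' @param rules Motif rule set: any of `"loop"`, `"triloop"`,
#'   `"internal_symmetry"`.
#' @return Data frame with columns `motif`, `n`, `mean`, `sd`.
#' @export
motif_aggregate <- function(values, structures,
                            rules = c("loop", "triloop",
                                      "internal_symmetry")) {
  known <- c("loop", "triloop", "internal_symmetry")
  bad <- setdiff(rules, known)
  if (length(bad)) {
    stop("unknown motif rule(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(values) != length(structures)) {
    stop("values and structures lengths differ", call. = FALSE)
  }
  pools <- list()
  add <- function(bin, v) pools[[bin]] <<- c(pools[[bin]], v)
  for (i in seq_along(values)) {
    det <- .annotate_details(as_pair_table(structures[[i]]))
    v <- values[[i]]
    idx <- seq_along(v)
    if (length(v) > length(det$classes)) {
      stop(sprintf("values longer than structure for construct %d", i),
           call. = FALSE)
    }
    cl <- det$classes[idx]
    if ("loop" %in% rules) {
      for (b in unique(cl)) add(b, v[cl == b])
    }
    if ("triloop" %in% rules) {
      tri <- cl == "H" & !is.na(det$hairpin_len[idx]) &
        det$hairpin_len[idx] == 3L
      if (any(tri)) add("triloop", v[tri])
    }
    if ("internal_symmetry" %in% rules) {
      isI <- cl == "I"
      sym <- det$internal_sym[idx]
      if (any(isI & sym %in% TRUE)) {
        add("internal_symmetric", v[isI & sym %in% TRUE])
      }
      if (any(isI & sym %in% FALSE)) {
        add("internal_asymmetric", v[isI & sym %in% FALSE])
      }
    }
  }
  data.frame(
    motif = names(pools),
    n = vapply(pools, length, 0L),
    mean = vapply(pools, mean, 0),
    sd = vapply(pools, stats::sd, 0),
    row.names = NULL)
}

#' Spearman rank correlation with a two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @param exact Use the exact null distribution (only for small samples
#'   without ties); default is the asymptotic t approximation.
#' @return List with elements `rho` and `p_value`.
#' @export
rank_correlation <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation is undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = exact,
                        alternative = "two.sided")
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
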