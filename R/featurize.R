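# Windowed one-hot featurization of sequence + loop-type context.

SEQ_ALPHABET <- c("A", "C", "G", "U")
STRUCT_ALPHABET <- c("H", "E", "I", "M", "B", "S")

#' Construct a windowed sequence/structure featurizer
#'
#' Describes the one-hot featurization used by the DegScore model family:
#' for each offset k in `[-window, window]` around a position, one indicator
#' per nucleotide identity (A, C, G, U) and one per loop type
#' (H, E, I, M, B, S). Offsets that fall outside the sequence contribute
#' all-zero blocks. By default the exterior-loop class `X` is encoded as `E`,
#' reflecting the biophysical similarity of the two exterior categories.
#'
#' @param window Window half-width w (non-negative integer; default 12).
#' @param merge_x_into_e Encode loop class `X` as `E` (default `TRUE`).
#' @return An object of class `window_featurizer`.
#' @export
window_featurizer <- function(window = 12L, merge_x_into_e = TRUE) {
  window <- as.integer(window)
  if (is.na(window) || window < 0L) {
    stop("window half-width must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(window = window,
         seq_alphabet = SEQ_ALPHABET,
         struct_alphabet = STRUCT_ALPHABET,
         merge_x_into_e = isTRUE(merge_x_into_e)),
    class = "window_featurizer")
}

#' @export
print.window_featurizer <- function(x, ...) {
  cat(sprintf(
    "window featurizer: w = %d, %d features per position (X->E: %s)\n",
    x$window, n_features(x), x$merge_x_into_e))
  invisible(x)
}

# number of feature columns (excluding the intercept)
n_features <- function(fz) {
  (2L * fz$window + 1L) *
    (length(fz$seq_alphabet) + length(fz$struct_alphabet))
}

feature_names <- function(fz) {
  offsets <- -fz$window:fz$window
  as.vector(vapply(
    offsets,
    function(k) paste0(k, ":", c(fz$seq_alphabet, fz$struct_alphabet)),
    character(length(fz$seq_alphabet) + length(fz$struct_alphabet))))
}

#' Number of free parameters of the windowed linear degradation model
#'
#' A window of half-width w covers 2w + 1 positions, each contributing 4
#' sequence indicators and 6 loop-type indicators, plus one intercept:
#' (2w + 1) x 10 + 1 parameters. For the published default w = 12 this
#' gives 251.
#'
#' @param w Window half-width (non-negative integer).
#' @return Integer parameter count.
#' @examples
#' count_parameters(12)  # 251
#' @export
count_parameters <- function(w) {
  w <- as.integer(w)
  if (length(w) != 1L || is.na(w) || w < 0L) {
    stop("w must be a single non-negative integer", call. = FALSE)
  }
  (2L * w + 1L) * 10L + 1L
}

#' Build the one-hot window feature matrix for one construct
#'
#' One row per nucleotide; columns are the flattened (offset, indicator)
#' grid of the featurizer. Each in-bounds offset contributes exactly one
#' sequence indicator and one loop-type indicator, so an interior row of a
#' long sequence has row sum 2(2w + 1).
#'
#' @param sequence RNA sequence over A/C/G/U.
#' @param loops Loop-type annotation string (same length as `sequence`),
#'   e.g. from [annotate_loop_types()]. If `NULL`, `structure` must be given
#'   instead and is annotated on the fly.
#' @param fz A [window_featurizer()].
#' @param structure Optional dot-bracket string used when `loops` is `NULL`.
#' @return Integer 0/1 matrix with `nchar(sequence)` rows and
#'   `(2w + 1) * 10` named columns.
#' @export
featurize <- function(sequence, loops = NULL, fz = window_featurizer(),
                      structure = NULL) {
  stopifnot(inherits(fz, "window_featurizer"))
  if (is.null(loops)) {
    if (is.null(structure)) {
      stop("either loops or structure must be supplied", call. = FALSE)
    }
    loops <- annotate_loop_types(structure)
  }
  sq <- chars(toupper(sequence))
  lp <- chars(loops)
  n <- length(sq)
  if (length(lp) != n) {
    stop("sequence and loop annotation lengths differ", call. = FALSE)
  }
  bad <- which(!sq %in% fz$seq_alphabet)
  if (length(bad)) {
    stop(sprintf("illegal sequence character '%s' at position %d",
                 sq[bad[1]], bad[1]), call. = FALSE)
  }
  if (fz$merge_x_into_e) lp[lp == "X"] <- "E"
  bad <- which(!lp %in% c(fz$struct_alphabet, "X"))
  if (length(bad)) {
    stop(sprintf("illegal loop-type character '%s' at position %d",
                 lp[bad[1]], bad[1]), call. = FALSE)
  }
  s_idx <- match(sq, fz$seq_alphabet)
  l_idx <- match(lp, fz$struct_alphabet)   # NA only for unmerged X
  block <- length(fz$seq_alphabet) + length(fz$struct_alphabet)
  offsets <- -fz$window:fz$window
  M <- matrix(0L, n, (2L * fz$window + 1L) * block,
              dimnames = list(NULL, feature_names(fz)))
  rows <- seq_len(n)
  for (j in seq_along(offsets)) {
    src <- rows + offsets[j]
    ok <- src >= 1L & src <= n
    base <- (j - 1L) * block
    M[cbind(rows[ok], base + s_idx[src[ok]])] <- 1L
    lcol <- l_idx[src[ok]]
    keep <- !is.na(lcol)
    M[cbind(rows[ok][keep],
            base + length(fz$seq_alphabet) + lcol[keep])] <- 1L
  }
  M
}
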