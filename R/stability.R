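# Whole-molecule aggregation: summed degradation rates and half-lives.

#' Total degradation rate over a region
#'
#' The overall degradation rate of an mRNA is the sum of the degradation
#' rates of its individual dinucleotide linkages; restricting the sum to a
#' region scores only the linkages probed there.
#'
#' @param rates Numeric vector of per-linkage (or per-nucleotide) rates.
#' @param start,end 1-based inclusive bounds of the region (defaults: the
#'   whole vector).
#' @return The summed rate.
#' @export
total_rate <- function(rates, start = 1L, end = length(rates)) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > length(rates) || start > end) {
    stop("empty or out-of-bounds region", call. = FALSE)
  }
  sum(rates[start:end])
}

#' Half-life from a total degradation rate
#'
#' First-order decay: t_1/2 = ln(2) / k. The half-life is reported in the
#' reciprocal unit of the input rate.
#'
#' @param k_total Total degradation rate (must be positive).
#' @return Half-life.
#' @examples
#' half_life(log(2))    # 1
#' half_life(0.0231)    # ~30
#' @export
half_life <- function(k_total) {
  if (any(k_total <= 0)) {
    stop("half-life is undefined for non-positive total rates", call. = FALSE)
  }
  log(2) / k_total
}

#' Sum per-nucleotide predictions over per-construct regions
#'
#' Sums each construct's predicted per-nucleotide degradation over a stated
#' window (typically the RT-PCR-captured 5'UTR + CDS region). Predictions
#' should be computed on the full sequence first and summed afterwards, so
#' that interactions between untranslated regions and the CDS are reflected
#' in the windowed total.
#'
#' @param predictions Named list of full-length numeric prediction vectors,
#'   one per construct.
#' @param regions Data frame with columns `id`, `start`, `end` (1-based,
#'   inclusive).
#' @param length_normalize Also report the sum divided by region length
#'   (column `length_normalized_rate`).
#' @return Data frame with columns `id`, `region_start`, `region_end`,
#'   `k_total`, `half_life` and, when `length_normalize` is `TRUE`,
#'   `length_normalized_rate`.
#' @export
sum_region_predictions <- function(predictions, regions,
                                   length_normalize = FALSE) {
  stopifnot(is.data.frame(regions),
            all(c("id", "start", "end") %in% names(regions)))
  missing <- setdiff(regions$id, names(predictions))
  if (length(missing)) {
    stop("no predictions for id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  k <- mapply(function(id, s, e) total_rate(predictions[[id]], s, e),
              regions$id, regions$start, regions$end)
  len <- regions$end - regions$start + 1L
  out <- data.frame(id = regions$id,
                    region_start = regions$start,
                    region_end = regions$end,
                    k_total = as.numeric(k),
                    half_life = ifelse(k > 0, log(2) / k, NA_real_),
                    row.names = NULL)
  if (length_normalize) out$length_normalized_rate <- out$k_total / len
  out
}
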