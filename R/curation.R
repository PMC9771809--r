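# Dataset curation: signal-to-noise filtering and clustering-based
# train / public-test / private-test splits.

#' Construct a signal-to-noise filter policy
#'
#' Records pass the filter when, over the min/max channels, every value is
#' strictly above `min_value` and strictly below `max_value`, and the
#' signal-to-noise ratio of the SN channel (see [sn_ratio()]) is strictly
#' above `sn_threshold`.
#'
#' @param min_value Lower value threshold (strict `>`; default 0.5).
#' @param max_value Upper value threshold (strict `<`; default 20).
#' @param sn_threshold Signal-to-noise threshold (strict `>`; default 1.0).
#' @param channels_minmax Channels whose values are screened against
#'   `min_value`/`max_value`; default: all degradation channels present.
#' @param channel_sn Channel whose signal-to-noise ratio is screened;
#'   default SHAPE reactivity.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_value = 0.5, max_value = 20,
                          sn_threshold = 1.0,
                          channels_minmax = CHANNELS_DEG,
                          channel_sn = "reactivity") {
  structure(list(min_value = min_value, max_value = max_value,
                 sn_threshold = sn_threshold,
                 channels_minmax = channels_minmax,
                 channel_sn = channel_sn),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf(
    "filter policy: values in (%g, %g) on [%s]; SN(%s) > %g\n",
    x$min_value, x$max_value, paste(x$channels_minmax, collapse = ", "),
    x$channel_sn, x$sn_threshold))
  invisible(x)
}

#' Flag records by the signal-to-noise filter
#'
#' Evaluates the filter policy on every record and sets its `SN_filter`
#' field to 1 (pass) or 0 (fail). Records are retained either way — failing
#' records stay in the dataset, flagged, so downstream consumers can decide
#' whether to train on them. The record's `signal_to_noise` field is set to
#' the SN ratio of the policy's SN channel.
#'
#' Only channels actually present on a record are screened; channels named
#' by the policy but absent from a record (for example the 7-day conditions
#' in a reduced-channel dataset) are skipped, except that a record carrying
#' none of the min/max channels, or lacking the SN channel, is an error.
#'
#' @param records List of RNA records.
#' @param policy A [filter_policy()].
#' @return The records, with `SN_filter` and `signal_to_noise` set.
#' @export
apply_sn_filter <- function(records, policy = filter_policy()) {
  lapply(records, function(r) {
    present <- intersect(policy$channels_minmax, names(r))
    if (!length(present)) {
      stop(sprintf("record '%s' carries none of the min/max channels (%s)",
                   r$id %||% "?",
                   paste(policy$channels_minmax, collapse = ", ")),
           call. = FALSE)
    }
    vals <- unlist(r[present], use.names = FALSE)
    if (is.null(r[[policy$channel_sn]]) ||
        is.null(r[[error_field(policy$channel_sn)]])) {
      stop(sprintf("record '%s' lacks channel '%s' or its error array",
                   r$id %||% "?", policy$channel_sn), call. = FALSE)
    }
    sn <- sn_ratio(as.numeric(r[[policy$channel_sn]]),
                   as.numeric(r[[error_field(policy$channel_sn)]]))
    r$signal_to_noise <- sn
    r$SN_filter <- as.integer(
      min(vals) > policy$min_value &&
        max(vals) < policy$max_value &&
        sn > policy$sn_threshold)
    r
  })
}

#' Hierarchically cluster sequences at a cophenetic cut
#'
#' Computes pairwise sequence distances (Levenshtein edit distance
#' normalized by the longer sequence, or Hamming for equal lengths),
#' builds an agglomerative dendrogram and cuts it at the given cophenetic
#' height. Ward linkage follows the common-library convention of applying
#' Ward's criterion to a precomputed distance matrix (`hclust` method
#' `"ward.D2"`); average linkage is available as a well-defined alternative
#' for non-Euclidean distances. Clustering is deterministic given the input
#' order (ties broken by `hclust`'s ordering).
#'
#' @param sequences Character vector of sequences (names become ids;
#'   unnamed input is labelled `seq_1`, `seq_2`, ...).
#' @param linkage_method `"ward"` (default) or `"average"`.
#' @param cut Cophenetic height at which the dendrogram is cut
#'   (default 0.5).
#' @param distance `"levenshtein"` (default) or `"hamming"` (equal lengths
#'   only).
#' @return List with `labels` (named integer cluster labels), `sizes`
#'   (per-id size of its cluster) and `tree` (the `hclust` object, `NULL`
#'   for a single sequence).
#' @export
cluster_sequences <- function(sequences, linkage_method = c("ward", "average"),
                              cut = 0.5,
                              distance = c("levenshtein", "hamming")) {
  linkage_method <- match.arg(linkage_method)
  distance <- match.arg(distance)
  n <- length(sequences)
  if (!n) stop("no sequences to cluster", call. = FALSE)
  ids <- names(sequences) %||% paste0("seq_", seq_len(n))
  if (is.null(names(sequences))) names(sequences) <- ids
  if (n == 1L) {
    lab <- stats::setNames(1L, ids)
    return(list(labels = lab, sizes = stats::setNames(1L, ids), tree = NULL))
  }
  D <- sequence_distance_matrix(sequences, distance)
  hc <- stats::hclust(stats::as.dist(D),
                      method = if (linkage_method == "ward") "ward.D2"
                               else "average")
  labels <- stats::cutree(hc, h = cut)
  names(labels) <- ids
  sizes <- stats::setNames(as.integer(table(labels))[labels], ids)
  list(labels = labels, sizes = sizes, tree = hc)
}

# Pairwise normalized sequence distances.
sequence_distance_matrix <- function(sequences,
                                     distance = c("levenshtein", "hamming")) {
  distance <- match.arg(distance)
  n <- length(sequences)
  len <- nchar(sequences)
  if (distance == "hamming") {
    if (length(unique(len)) != 1L) {
      stop("hamming distance requires equal-length sequences", call. = FALSE)
    }
    mats <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- sum(mats[i, ] != mats[j, ]) / len[1]
      }
    }
  } else {
    D <- utils::adist(sequences) / outer(len, len, pmax)
  }
  dimnames(D) <- list(names(sequences), names(sequences))
  D
}

#' Assign train / public-test / private-test splits from clusters
#'
#' Implements the blind-test curation rule: every member of a cluster with
#' at most three members goes to the private test set; the private set is
#' then topped up with one randomly chosen member from each of a random
#' selection of the larger clusters until its target size is met; the
#' remaining records are randomly partitioned into the training and public
#' test sets. Fully reproducible given `seed`.
#'
#' @param clusters Result of [cluster_sequences()] (or any list with named
#'   `labels`).
#' @param target_counts List with elements `private_test`, `public_test`
#'   and optionally `train` (default: all remaining records).
#' @param seed RNG seed.
#' @param small_cluster_max Largest cluster size swept wholly into the
#'   private test set (default 3).
#' @return An object of class `split_assignment`: data frame with columns
#'   `id`, `cluster`, `cluster_size`, `split`.
#' @export
assign_splits <- function(clusters, target_counts, seed = 1L,
                          small_cluster_max = 3L) {
  labels <- clusters$labels
  ids <- names(labels)
  if (is.null(ids)) stop("cluster labels must be named by record id",
                         call. = FALSE)
  sizes_by_cluster <- table(labels)
  size_of <- as.integer(sizes_by_cluster[as.character(labels)])
  names(size_of) <- ids
  forced <- ids[size_of <= small_cluster_max]

  n_private <- target_counts$private_test
  if (is.null(n_private)) stop("target_counts$private_test is required",
                               call. = FALSE)
  if (n_private < length(forced)) {
    stop(sprintf(
      "private_test target %d is below the %d members forced in by clusters of size <= %d",
      n_private, length(forced), small_cluster_max), call. = FALSE)
  }
  big_clusters <- names(sizes_by_cluster)[sizes_by_cluster > small_cluster_max]
  need <- n_private - length(forced)
  if (need > length(big_clusters)) {
    stop(sprintf(
      "private_test target %d infeasible: at most %d achievable (one member per larger cluster plus %d forced)",
      n_private, length(forced) + length(big_clusters), length(forced)),
      call. = FALSE)
  }

  with_seed(seed, {
    topup <- character()
    if (need > 0L) {
      chosen <- sample(big_clusters, need)
      topup <- vapply(chosen, function(cl) {
        members <- ids[labels == as.integer(cl)]
        members[sample.int(length(members), 1L)]
      }, "")
    }
    private <- c(forced, unname(topup))
    rest <- setdiff(ids, private)
    n_public <- target_counts$public_test %||% 0L
    n_train <- target_counts$train %||% (length(rest) - n_public)
    if (n_public + n_train != length(rest)) {
      stop(sprintf(
        "train + public_test targets (%d) must cover the %d records left after private selection",
        n_public + n_train, length(rest)), call. = FALSE)
    }
    split <- stats::setNames(rep("train", length(ids)), ids)
    split[private] <- "private_test"
    if (n_public > 0L) split[sample(rest, n_public)] <- "public_test"
    structure(
      data.frame(id = ids, cluster = as.integer(labels),
                 cluster_size = unname(size_of), split = unname(split[ids]),
                 row.names = NULL),
      class = c("split_assignment", "data.frame"))
  })
}

#' @export
print.split_assignment <- function(x, ...) {
  tab <- table(x$split)
  cat("split assignment: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  invisible(as.data.frame(x))
}
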