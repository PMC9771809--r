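# The per-construct record: one RNA with its structure features and
# per-channel measurement + error arrays (competition-dump field names).

#' Construct a validated RNA measurement record
#'
#' @param id Construct identifier.
#' @param sequence RNA sequence (A/C/G/U).
#' @param structure Dot-bracket secondary structure, same length.
#' @param predicted_loop_type Loop-type annotation string (computed from
#'   `structure` when omitted).
#' @param seq_scored Number of scored 5'-prefix positions (default: the
#'   length of the first channel array, or the full length).
#' @param ... Channel arrays (`reactivity`, `deg_Mg_pH10`, `deg_Mg_50C`,
#'   `deg_pH10`, `deg_50C`) and their error arrays (`reactivity_error`,
#'   `deg_error_Mg_pH10`, ...), each of length `seq_scored`; optionally
#'   `signal_to_noise` and `SN_filter`.
#' @return An object of class `rna_record`.
#' @export
rna_record <- function(id, sequence, structure, predicted_loop_type = NULL,
                       seq_scored = NULL, ...) {
  extra <- list(...)
  sequence <- toupper(sequence)
  if (is.null(predicted_loop_type)) {
    predicted_loop_type <- annotate_loop_types(structure)
  }
  channels <- intersect(CHANNELS_ALL, names(extra))
  if (is.null(seq_scored)) {
    seq_scored <- if (length(channels)) length(extra[[channels[1]]]) else
      nchar(sequence)
  }
  r <- c(list(id = id, sequence = sequence, structure = structure,
              predicted_loop_type = predicted_loop_type,
              seq_length = nchar(sequence),
              seq_scored = as.integer(seq_scored)),
         extra)
  class(r) <- "rna_record"
  validate_rna_record(r)
}

#' Validate the invariants of an RNA record
#'
#' Checks that sequence, structure and loop annotation agree in length with
#' `seq_length`, that every present channel array and its error array have
#' `seq_scored` entries, that `seq_scored <= seq_length`, and that errors
#' are non-negative.
#'
#' @param r An `rna_record` (or plain list with the same fields).
#' @return The record, invisibly classed as `rna_record`.
#' @export
validate_rna_record <- function(r) {
  id <- r$id %||% "?"
  n <- r$seq_length %||% nchar(r$sequence)
  for (f in c("sequence", "structure", "predicted_loop_type")) {
    if (!is.null(r[[f]]) && nchar(r[[f]]) != n) {
      stop(sprintf("record '%s': %s length %d != seq_length %d",
                   id, f, nchar(r[[f]]), n), call. = FALSE)
    }
  }
  if (r$seq_scored > n) {
    stop(sprintf("record '%s': seq_scored %d exceeds seq_length %d",
                 id, r$seq_scored, n), call. = FALSE)
  }
  for (ch in intersect(CHANNELS_ALL, names(r))) {
    if (length(r[[ch]]) != r$seq_scored) {
      stop(sprintf("record '%s': channel '%s' has %d values, expected %d",
                   id, ch, length(r[[ch]]), r$seq_scored), call. = FALSE)
    }
    ef <- error_field(ch)
    if (!is.null(r[[ef]])) {
      if (length(r[[ef]]) != r$seq_scored) {
        stop(sprintf("record '%s': error array '%s' has %d values, expected %d",
                     id, ef, length(r[[ef]]), r$seq_scored), call. = FALSE)
      }
      if (any(r[[ef]] < 0)) {
        stop(sprintf("record '%s': negative errors in '%s'", id, ef),
             call. = FALSE)
      }
    }
  }
  class(r) <- "rna_record"
  invisible(r)
}

#' @export
print.rna_record <- function(x, ...) {
  cat(sprintf("RNA record '%s': %d nt (%d scored), channels: %s\n",
              x$id, x$seq_length, x$seq_scored,
              paste(intersect(CHANNELS_ALL, names(x)), collapse = ", ")))
  invisible(x)
}

#' Extract measured-value and error matrices from records
#'
#' Builds the prediction-set-shaped containers used by [mcrmse()],
#' [average_predictions()] and [ga_select()]: one scored-positions-by-
#' channels matrix per construct.
#'
#' @param records List of RNA records.
#' @param channels Channels to extract (default: all present on the first
#'   record).
#' @param what `"values"` or `"errors"`.
#' @return Named list of matrices.
#' @export
records_to_matrices <- function(records, channels = NULL,
                                what = c("values", "errors")) {
  what <- match.arg(what)
  if (is.null(channels)) {
    channels <- intersect(CHANNELS_ALL, names(records[[1]]))
  }
  out <- lapply(records, function(r) {
    m <- vapply(channels, function(ch) {
      f <- if (what == "values") ch else error_field(ch)
      if (is.null(r[[f]])) {
        stop(sprintf("record '%s' lacks field '%s'", r$id %||% "?", f),
             call. = FALSE)
      }
      as.numeric(r[[f]])
    }, numeric(r$seq_scored))
    colnames(m) <- channels
    m
  })
  names(out) <- vapply(records, function(r) r$id, "")
  out
}
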