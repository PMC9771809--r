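# Readers and writers: JSON record files (competition-dump dialect), FASTA,
# prediction CSVs, whitespace bpp matrices, model and ensemble-spec JSON,
# split CSVs.
#
# File conventions: JSON lines is the canonical dataset dialect; positions
# in CSV files are 0-based (documented in a header comment); the R API is
# 1-based throughout.

#' Read RNA records from a JSON file
#'
#' @param path File of JSON records, either one object per line
#'   (`json_lines`, canonical) or a single JSON array (`json_array`).
#' @param dialect `"json_lines"` or `"json_array"`.
#' @return List of validated `rna_record` objects (empty, with a warning,
#'   for an empty file).
#' @export
read_rna_records <- function(path, dialect = c("json_lines", "json_array")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  raw <- if (dialect == "json_lines") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
               error = function(e) {
                 stop(sprintf("malformed JSON on line %d of %s: %s",
                              i, path, conditionMessage(e)), call. = FALSE)
               })
    })
  } else {
    parsed <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                       error = function(e) {
                         stop(sprintf("malformed JSON in %s: %s", path,
                                      conditionMessage(e)), call. = FALSE)
                       })
    parsed
  }
  if (!length(raw)) {
    warning(sprintf("no records in %s", path), call. = FALSE)
    return(list())
  }
  lapply(raw, function(r) validate_rna_record(as.list(r)))
}

#' Write RNA records to a JSON file
#'
#' @param records List of RNA records.
#' @param path Output path.
#' @param dialect `"json_lines"` (default) or `"json_array"`.
#' @export
write_rna_records <- function(records, path,
                              dialect = c("json_lines", "json_array")) {
  dialect <- match.arg(dialect)
  strip <- function(r) unclass(r)
  if (dialect == "json_lines") {
    con <- file(path, "w")
    on.exit(close(con))
    for (r in records) {
      writeLines(jsonlite::toJSON(strip(r), auto_unbox = TRUE, digits = NA,
                                  null = "null"), con)
    }
  } else {
    jsonlite::write_json(lapply(records, strip), path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' DNA-style `T`s are normalized to `U` (with a message when any were
#' present). Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    message("normalizing T to U in FASTA input")
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Write a prediction set to CSV
#'
#' Long format with columns `id`, `position` (0-based in the file),
#' `channel`, `value`, preceded by a comment line stating the position
#' convention.
#'
#' @param predictions A prediction set: named list of positions-by-channels
#'   matrices.
#' @param path Output path.
#' @export
write_predictions_csv <- function(predictions, path) {
  rows <- do.call(rbind, lapply(names(predictions), function(id) {
    m <- predictions[[id]]
    data.frame(id = id,
               position = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
               channel = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions are 0-based", con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Read a prediction set from CSV
#'
#' Expects the format of [write_predictions_csv()]; every (id, channel)
#' must cover a contiguous 0-based position range starting at 0, otherwise
#' a completeness error is raised.
#'
#' @param path CSV path.
#' @return Named list of positions-by-channels matrices.
#' @export
read_predictions_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(id = "character",
                                       channel = "character"))
  need <- c("id", "position", "channel", "value")
  if (!all(need %in% names(df))) {
    stop("prediction CSV must have columns id, position, channel, value",
         call. = FALSE)
  }
  out <- lapply(split(df, df$id), function(d) {
    chans <- sort(unique(d$channel))
    npos <- length(unique(d$position))
    m <- matrix(NA_real_, npos, length(chans),
                dimnames = list(NULL, chans))
    for (ch in chans) {
      dc <- d[d$channel == ch, ]
      if (!setequal(dc$position, 0:(npos - 1L)) || nrow(dc) != npos) {
        stop(sprintf(
          "incomplete predictions for id '%s', channel '%s': expected positions 0..%d",
          d$id[1], ch, npos - 1L), call. = FALSE)
      }
      m[dc$position + 1L, ch] <- dc$value
    }
    m
  })
  out[unique(df$id)]
}

#' Read a base-pair probability matrix from whitespace-delimited text
#'
#' Format: a single-line header giving N, then N rows of N probabilities.
#'
#' @param path Matrix file.
#' @return N x N numeric matrix.
#' @export
read_bpp_matrix <- function(path) {
  nums <- scan(path, quiet = TRUE)
  n <- nums[1]
  if (n != round(n) || length(nums) != 1 + n * n) {
    stop(sprintf("bpp file %s: expected header N then N*N entries", path),
         call. = FALSE)
  }
  matrix(nums[-1], nrow = n, byrow = TRUE)
}

#' Write a base-pair probability matrix
#'
#' @param bpp Square numeric matrix.
#' @param path Output path.
#' @export
write_bpp_matrix <- function(bpp, path) {
  stopifnot(is.matrix(bpp), nrow(bpp) == ncol(bpp))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(bpp)), con)
  utils::write.table(bpp, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a linear DegScore model to JSON
#'
#' Stores the window, alphabets, coefficient table (keyed
#' `"offset:indicator"`), intercept, channel and training metadata.
#' Gradient-boosted models are not JSON-serializable here; save those with
#' `xgboost::xgb.save()`.
#'
#' @param model A linear `degscore` model.
#' @param path Output path.
#' @export
write_degscore <- function(model, path) {
  stopifnot(inherits(model, "degscore"))
  if (model$method != "ridge") {
    stop("only linear models serialize to JSON; use xgboost::xgb.save() for boosted models",
         call. = FALSE)
  }
  fz <- model$featurizer
  doc <- list(model = "degscore_linear",
              window = fz$window,
              sequence_alphabet = fz$seq_alphabet,
              structure_alphabet = fz$struct_alphabet,
              merge_x_into_e = fz$merge_x_into_e,
              channel = model$channel,
              lambda = model$lambda,
              beta0 = model$intercept,
              beta = as.list(model$coefficients),
              training = list(n_obs = model$n_obs,
                              n_records = model$n_records,
                              rmse = model$training_rmse))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a linear DegScore model from JSON
#'
#' Accepts files written by [write_degscore()] or any external coefficient
#' table in the same layout.
#'
#' @param path JSON path.
#' @return A `degscore` object.
#' @export
read_degscore <- function(path) {
  doc <- jsonlite::fromJSON(path)
  fz <- window_featurizer(doc$window, isTRUE(doc$merge_x_into_e))
  beta <- unlist(doc$beta)
  expect <- feature_names(fz)
  if (!setequal(names(beta), expect)) {
    stop("model file coefficient keys do not match the featurizer grid",
         call. = FALSE)
  }
  structure(list(channel = doc$channel, featurizer = fz, method = "ridge",
                 lambda = doc$lambda, intercept = doc$beta0,
                 coefficients = beta[expect],
                 n_obs = doc$training$n_obs %||% NA_integer_,
                 n_records = doc$training$n_records %||% NA_integer_,
                 training_rmse = doc$training$rmse %||% NA_real_,
                 call = match.call()),
            class = "degscore")
}

#' Serialize an ensemble spec to JSON
#'
#' @param spec An `ensemble_spec`.
#' @param path Output path.
#' @export
write_ensemble_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ensemble_spec"))
  jsonlite::write_json(
    list(member_ids = spec$member_ids,
         weights = as.list(spec$weights),
         objective_score = spec$objective_score),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ensemble spec from JSON
#'
#' @param path JSON path.
#' @return An `ensemble_spec`.
#' @export
read_ensemble_spec <- function(path) {
  doc <- jsonlite::fromJSON(path)
  w <- unlist(doc$weights)
  structure(list(member_ids = doc$member_ids,
                 weights = w[doc$member_ids],
                 objective_score = doc$objective_score),
            class = "ensemble_spec")
}

#' Write a split assignment to CSV
#'
#' @param assignment A `split_assignment` from [assign_splits()].
#' @param path Output path.
#' @export
write_splits <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE)
  invisible(path)
}

#' Read a split assignment from CSV
#'
#' @param path CSV path.
#' @return A `split_assignment` data frame.
#' @export
read_splits <- function(path) {
  df <- utils::read.csv(path, colClasses = c(id = "character",
                                             split = "character"))
  structure(df, class = c("split_assignment", "data.frame"))
}
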