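# Internal helpers shared across modules.

# Measurement channel vocabulary (field names follow the public competition-dump dialect).
CHANNELS_DEG <- c("deg_Mg_pH10", "deg_Mg_50C", "deg_pH10", "deg_50C")
CHANNELS_ALL <- c("reactivity", CHANNELS_DEG)

ERROR_FIELDS <- c(
  reactivity   = "reactivity_error",
  deg_Mg_pH10  = "deg_error_Mg_pH10",
  deg_Mg_50C   = "deg_error_Mg_50C",
  deg_pH10     = "deg_error_pH10",
  deg_50C      = "deg_error_50C"
)

#' Name of the error array matching a measurement channel
#'
#' @param channel Channel name, e.g. `"reactivity"` or `"deg_Mg_pH10"`.
#' @return The corresponding error-array field name, e.g. `"reactivity_error"`.
#' @export
error_field <- function(channel) {
  out <- ERROR_FIELDS[channel]
  if (anyNA(out)) {
    stop("unknown channel(s): ", paste(channel[is.na(out)], collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

# Evaluate `code` under a fixed RNG seed without clobbering the caller's RNG
# stream; a NULL seed leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# split a sequence string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
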