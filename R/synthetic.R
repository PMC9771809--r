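# Synthetic benchmark data: random constructs with a planted linear
# sequence+structure degradation signal, heteroscedastic counting-like
# noise and curation edge cases (filter failures, near-duplicates).

#' Configuration for the synthetic dataset generator
#'
#' The defaults emulate the regime of the crowdsourced in-line hydrolysis
#' datasets: 107-nt constructs scored over their first 68 nt, a constant
#' `GGAAA` 5' prefix, five measurement channels (SHAPE reactivity plus four
#' degradation conditions), per-position errors that grow with the square
#' root of the signal (Poisson-counting-like, with a floor keeping every
#' sigma positive), a shared per-position latent component that correlates
#' the channels, and motif effects making triloops the most reactive
#' context and asymmetric internal loops more degradation-prone than
#' symmetric ones.
#'
#' The planted per-channel linear models are drawn from `seed` in the
#' identifiable canonical form: coefficient vectors are projected onto the
#' orthocomplement of the window design's structural collinearity
#' directions (within each offset, sequence and loop indicators both sum to
#' the in-bounds flag, and the offset-0 sequence indicators sum to the
#' intercept column), so they are exactly recoverable by unpenalized least
#' squares.
#'
#' @param n_constructs Number of constructs.
#' @param length,scored_length Construct length and scored 5'-prefix length
#'   (defaults 107 / 68; the longer-round regime is 130 / 102).
#' @param gc_content Target GC fraction of the random portion.
#' @param prefix Constant 5' prefix (`NULL` for none; default `"GGAAA"`).
#' @param channels Measurement channel names (default: reactivity plus the
#'   four degradation conditions).
#' @param window Window half-width of the planted linear models.
#' @param beta_sd,intercept Scale of planted slopes and the planted
#'   intercept (per channel).
#' @param motif_effects Named additive offsets for `triloop`,
#'   `internal_symmetric`, `internal_asymmetric` positions.
#' @param noise_floor,noise_scale Per-position sd is
#'   `noise_floor + noise_scale * sqrt(max(signal, 0))`.
#' @param latent_sd Standard deviation of the per-position latent component
#'   shared by all channels.
#' @param fail_fraction Fraction of constructs whose errors are inflated so
#'   they fail the signal-to-noise filter.
#' @param duplicate_rate Fraction of constructs generated as near-copies of
#'   an earlier construct (`dup_mutations` point mutations).
#' @param dup_mutations Mutations applied to each injected near-duplicate.
#' @param pair_prob,min_hairpin Structure-sampler parameters: pairing
#'   propensity and minimum hairpin-loop length.
#' @param seed Seed fixing the entire dataset.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_constructs = 100L, length = 107L,
                             scored_length = 68L, gc_content = 0.5,
                             prefix = "GGAAA",
                             channels = CHANNELS_ALL,
                             window = 12L, beta_sd = 0.05, intercept = 2,
                             motif_effects = c(triloop = 0.6,
                                               internal_symmetric = 0.1,
                                               internal_asymmetric = 0.3),
                             noise_floor = 0.05, noise_scale = 0.15,
                             latent_sd = 0.1,
                             fail_fraction = 0, duplicate_rate = 0,
                             dup_mutations = 2L,
                             pair_prob = 0.55, min_hairpin = 3L,
                             seed = 1L) {
  if (scored_length > length) {
    stop("scored_length cannot exceed length", call. = FALSE)
  }
  if (gc_content < 0 || gc_content > 1) {
    stop("gc_content must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic config: %d constructs, %d nt (%d scored), %d channels, seed %d\n",
    x$n_constructs, x$length, x$scored_length, length(x$channels), x$seed))
  invisible(x)
}

# Known exact collinearity directions of the augmented (intercept + window
# one-hot) design, as columns of an orthonormal basis. Always present:
# within each offset the sequence indicators and the loop indicators both
# sum to the in-bounds flag (2w+1 directions), and at offset 0 that flag is
# the intercept column (1 more). When only a scored 5' prefix that ends at
# least w positions before the 3' end is ever observed (the usual regime:
# seq_scored + w <= seq_length), every non-negative offset is always
# in-bounds too, adding one direction per k in 1..w.
eq5_null_basis <- function(fz, scored_tail_free = FALSE) {
  block <- length(fz$seq_alphabet) + length(fz$struct_alphabet)
  n_off <- 2L * fz$window + 1L
  p <- 1L + n_off * block
  n_extra <- if (scored_tail_free) fz$window else 0L
  B <- matrix(0, p, n_off + 1L + n_extra)
  for (j in seq_len(n_off)) {
    base <- 1L + (j - 1L) * block
    B[base + seq_along(fz$seq_alphabet), j] <- 1
    B[base + length(fz$seq_alphabet) + seq_along(fz$struct_alphabet), j] <- -1
  }
  j0 <- fz$window + 1L
  B[1L, n_off + 1L] <- 1
  B[1L + (j0 - 1L) * block + seq_along(fz$seq_alphabet), n_off + 1L] <- -1
  if (scored_tail_free) {
    for (k in seq_len(fz$window)) {
      col <- n_off + 1L + k
      B[1L, col] <- -1
      B[1L + (j0 + k - 1L) * block + seq_along(fz$seq_alphabet), col] <- 1
    }
  }
  qr.Q(qr(B))
}

# Project an augmented coefficient vector c(intercept, beta) onto the
# orthocomplement of the structural null directions (identifiable form).
canonical_coefficients <- function(theta, fz, scored_tail_free = FALSE) {
  Q <- eq5_null_basis(fz, scored_tail_free)
  drop(theta - Q %*% crossprod(Q, theta))
}

#' Planted linear model of a synthetic configuration
#'
#' Reconstructs the ground-truth linear model for one channel, as a fitted
#' `degscore`-classed object usable with [predict()] and [coef()].
#'
#' @param cfg A [synthetic_config()].
#' @param channel One of `cfg$channels`.
#' @return A `degscore` object (method `"ridge"`).
#' @export
planted_model <- function(cfg, channel) {
  stopifnot(inherits(cfg, "synthetic_config"))
  idx <- match(channel, cfg$channels)
  if (is.na(idx)) stop(sprintf("channel '%s' not in the config", channel),
                       call. = FALSE)
  fz <- window_featurizer(cfg$window)
  theta <- planted_thetas(cfg)[[idx]]
  structure(list(channel = channel, featurizer = fz, method = "ridge",
                 lambda = 0, intercept = theta[1],
                 coefficients = stats::setNames(theta[-1],
                                                feature_names(fz)),
                 n_obs = 0L, n_records = 0L,
                 training_rmse = NA_real_,
                 call = match.call()),
            class = "degscore")
}

#' Generate random RNA sequences
#'
#' @param n Number of sequences.
#' @param length Sequence length (including the prefix).
#' @param gc_content Target GC fraction of the random portion.
#' @param prefix Constant 5' prefix (`NULL` for none).
#' @param seed RNG seed (`NULL`: use the current stream).
#' @return Named character vector (`synth_0001`, ...).
#' @export
generate_sequences <- function(n, length = 107L, gc_content = 0.5,
                               prefix = "GGAAA", seed = NULL) {
  if (gc_content < 0 || gc_content > 1) {
    stop("gc_content must lie in [0, 1]", call. = FALSE)
  }
  prefix <- prefix %||% ""
  if (nchar(prefix) > length) stop("prefix longer than sequence",
                                   call. = FALSE)
  n_rand <- length - nchar(prefix)
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, U = (1 - gc_content) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste0(prefix, paste(sample(names(probs), n_rand, replace = TRUE,
                                  prob = probs), collapse = ""))
    }, "")
    names(seqs) <- sprintf("synth_%04d", seq_len(n))
    seqs
  })
}

CAN_PAIR <- list(A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")

#' Sample a random nested secondary structure for a sequence
#'
#' Draws a valid nested structure with Watson-Crick/wobble pairs only
#' (AU, GC, GU) and hairpin loops of at least `min_hairpin` nucleotides.
#' This is a stochastic stand-in for a thermodynamic fold: it produces
#' structurally valid input features without an external folding engine,
#' and any externally computed MFE structure can be supplied in its place
#' wherever a dot-bracket string is accepted.
#'
#' @param sequence RNA sequence over A/C/G/U.
#' @param seed RNG seed (`NULL`: current stream).
#' @param pair_prob Probability of attempting a pair at each open position.
#' @param min_hairpin Minimum hairpin-loop length (default 3).
#' @return Dot-bracket string.
#' @export
sample_structure <- function(sequence, seed = NULL, pair_prob = 0.55,
                             min_hairpin = 3L) {
  sq <- chars(toupper(sequence))
  n <- length(sq)
  partner <- rep(NA_integer_, n)
  fold_region <- function(lo, hi) {
    i <- lo
    while (i <= hi) {
      if (!is.na(partner[i])) { i <- i + 1L; next }
      lo_j <- i + min_hairpin + 1L
      if (lo_j <= hi && stats::runif(1) < pair_prob) {
        cand <- lo_j:hi
        ok <- cand[sq[cand] %in% CAN_PAIR[[sq[i]]] & is.na(partner[cand])]
        if (length(ok)) {
          j <- ok[sample.int(length(ok), 1L)]
          partner[i] <<- j
          partner[j] <<- i
          fold_region(i + 1L, j - 1L)
          i <- j + 1L
          next
        }
      }
      i <- i + 1L
    }
  }
  with_seed(seed, fold_region(1L, n))
  db <- rep(".", n)
  db[!is.na(partner) & partner > seq_len(n)] <- "("
  db[!is.na(partner) & partner < seq_len(n)] <- ")"
  paste(db, collapse = "")
}

# Planted per-channel coefficient vectors of a config (augmented form).
planted_thetas <- function(cfg) {
  fz <- window_featurizer(cfg$window)
  tail_free <- cfg$scored_length + cfg$window <= cfg$length
  with_seed(cfg$seed, {
    lapply(seq_along(cfg$channels), function(i) {
      raw <- c(cfg$intercept, stats::rnorm(n_features(fz), 0, cfg$beta_sd))
      canonical_coefficients(raw, fz, tail_free)
    })
  })
}

#' Plant per-channel measurements for one construct
#'
#' Evaluates the configuration's planted linear models on the construct,
#' adds the motif offsets and the shared latent component (the per-position
#' "true" signal), then corrupts the scored prefix with Gaussian noise
#' whose per-position sd follows the counting-noise-like model
#' `noise_floor + noise_scale * sqrt(max(truth, 0))`.
#'
#' @param sequence,structure The construct.
#' @param cfg A [synthetic_config()].
#' @param seed RNG seed for the latent and noise draws (`NULL`: current
#'   stream).
#' @return List with matrices `truth` (full length x channels), `values`
#'   and `errors` (scored length x channels).
#' @export
plant_measurements <- function(sequence, structure, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  fz <- window_featurizer(cfg$window)
  thetas <- planted_thetas(cfg)
  det <- .annotate_details(as_pair_table(structure))
  loops <- paste(det$classes, collapse = "")
  M <- featurize(sequence, loops, fz)
  n <- nrow(M)
  scored <- seq_len(min(cfg$scored_length, n))

  motif <- rep(0, n)
  eff <- cfg$motif_effects
  tri <- det$classes == "H" & !is.na(det$hairpin_len) & det$hairpin_len == 3L
  motif[tri] <- motif[tri] + (eff[["triloop"]] %||% 0)
  motif[det$classes == "I" & det$internal_sym %in% TRUE] <-
    eff[["internal_symmetric"]] %||% 0
  motif[det$classes == "I" & det$internal_sym %in% FALSE] <-
    eff[["internal_asymmetric"]] %||% 0

  with_seed(seed, {
    z <- if (cfg$latent_sd > 0) stats::rnorm(n, 0, cfg$latent_sd) else
      rep(0, n)
    truth <- vapply(thetas, function(th) {
      drop(M %*% th[-1]) + th[1] + motif + z
    }, numeric(n))
    colnames(truth) <- cfg$channels
    sigma <- cfg$noise_floor + cfg$noise_scale *
      sqrt(pmax(truth[scored, , drop = FALSE], 0))
    values <- truth[scored, , drop = FALSE] +
      stats::rnorm(length(sigma), 0, as.vector(sigma))
    list(truth = truth, values = values, errors = sigma)
  })
}

#' Generate a full synthetic dataset of RNA records
#'
#' Draws sequences (optionally with injected near-duplicates), samples a
#' nested structure for each, plants measurements from the configuration's
#' linear models, inflates the errors of a configurable fraction of
#' constructs so that they fail the signal-to-noise filter, and evaluates
#' the filter to set each record's `SN_filter` flag.
#'
#' @param cfg A [synthetic_config()].
#' @param path Optional output path; when given, records are also written
#'   as JSON lines (see [write_rna_records()]).
#' @return List of `rna_record` objects.
#' @export
make_dataset <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  records <- with_seed(cfg$seed, {
    seqs <- generate_sequences(cfg$n_constructs, cfg$length, cfg$gc_content,
                               cfg$prefix)
    n_dup <- round(cfg$duplicate_rate * cfg$n_constructs)
    if (n_dup > 0 && cfg$n_constructs > 1L) {
      dup_idx <- sample(2:cfg$n_constructs, min(n_dup, cfg$n_constructs - 1L))
      pre <- nchar(cfg$prefix %||% "")
      for (i in dup_idx) {
        src <- sample.int(i - 1L, 1L)
        s <- chars(seqs[[src]])
        pos <- sample((pre + 1L):length(s), cfg$dup_mutations)
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1L)
        seqs[[i]] <- paste(s, collapse = "")
      }
    }
    n_fail <- round(cfg$fail_fraction * cfg$n_constructs)
    fail_idx <- if (n_fail > 0) sample.int(cfg$n_constructs, n_fail) else
      integer()

    lapply(seq_len(cfg$n_constructs), function(i) {
      structure_db <- sample_structure(seqs[[i]], pair_prob = cfg$pair_prob,
                                       min_hairpin = cfg$min_hairpin)
      pm <- plant_measurements(seqs[[i]], structure_db, cfg)
      values <- pm$values
      errors <- pm$errors
      if (i %in% fail_idx) {
        # inflate uncertainties so mu/sigma averages well below 1
        errors <- pmax(abs(values), cfg$noise_floor) * 2.5
      }
      fields <- list(id = names(seqs)[i],
                     sequence = seqs[[i]],
                     structure = structure_db,
                     predicted_loop_type = annotate_loop_types(structure_db),
                     seq_length = cfg$length,
                     seq_scored = cfg$scored_length)
      for (j in seq_along(cfg$channels)) {
        ch <- cfg$channels[j]
        fields[[ch]] <- unname(values[, j])
        fields[[error_field(ch)]] <- unname(errors[, j])
      }
      structure(fields, class = "rna_record")
    })
  })
  pol <- filter_policy(channels_minmax = intersect(CHANNELS_DEG,
                                                   cfg$channels))
  all_positive <- all(vapply(records, function(r) {
    all(r[[error_field(pol$channel_sn)]] > 0)
  }, NA))
  records <- if (all_positive) {
    apply_sn_filter(records, pol)
  } else {
    # noiseless datasets have zero reported uncertainty; the SN ratio is
    # undefined there, so every record is kept with flag 1
    lapply(records, function(r) { r$SN_filter <- 1L; r })
  }
  if (!is.null(path)) write_rna_records(records, path)
  records
}
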