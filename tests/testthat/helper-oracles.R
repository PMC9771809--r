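# Shared fixtures and independent brute-force oracles used across tests.

# Small synthetic dataset helper (defaults tuned for test speed).
tiny_config <- function(n = 10, len = 50, scored = 40, window = 2,
                        seed = 101, ...) {
  synthetic_config(n_constructs = n, length = len, scored_length = scored,
                   window = window, seed = seed, ...)
}

# Noiseless variant: no measurement noise, latent or motif offsets, so
# measurements equal the planted linear model exactly.
noiseless_config <- function(n = 10, len = 50, scored = 40, window = 2,
                             seed = 101, ...) {
  tiny_config(n, len, scored, window, seed,
              noise_floor = 0, noise_scale = 0, latent_sd = 0,
              motif_effects = c(triloop = 0, internal_symmetric = 0,
                                internal_asymmetric = 0), ...)
}

# Breadth-first search over backbone + pair edges (independent of igraph).
bfs_distances <- function(pt) {
  n <- pt$length
  adj <- lapply(seq_len(n), function(i) {
    nb <- c(if (i > 1) i - 1L, if (i < n) i + 1L,
            if (!is.na(pt$partner[i])) pt$partner[i])
    nb
  })
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- lvl
      frontier <- nxt
    }
  }
  d
}

# Direct evaluation of the windowed linear model by explicit loops over
# offsets and indicator alphabets.
loop_eq5 <- function(sequence, loops, beta, beta0, w,
                     merge_x_into_e = TRUE) {
  sq <- strsplit(sequence, "")[[1]]
  lp <- strsplit(loops, "")[[1]]
  if (merge_x_into_e) lp[lp == "X"] <- "E"
  n <- length(sq)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- beta0
    for (k in -w:w) {
      j <- i + k
      if (j < 1 || j > n) next
      for (nt in c("A", "C", "G", "U")) {
        acc <- acc + beta[paste0(k, ":", nt)] * (sq[j] == nt)
      }
      for (s in c("H", "E", "I", "M", "B", "S")) {
        acc <- acc + beta[paste0(k, ":", s)] * (lp[j] == s)
      }
    }
    y[i] <- acc
  }
  y
}

# Double-loop evaluation of the MCRMSE definition.
loop_mcrmse <- function(measured, predicted) {
  chans <- colnames(measured[[1]])
  rmse <- numeric(length(chans))
  for (j in seq_along(chans)) {
    sq_sum <- 0; count <- 0
    for (id in names(measured)) {
      for (i in seq_len(nrow(measured[[id]]))) {
        sq_sum <- sq_sum + (measured[[id]][i, j] - predicted[[id]][i, j])^2
        count <- count + 1
      }
    }
    rmse[j] <- sqrt(sq_sum / count)
  }
  mean(rmse)
}

# Double-loop evaluation of the signal-to-noise definition.
loop_sn_ratio <- function(values, errors) {
  values <- as.matrix(values); errors <- as.matrix(errors)
  acc <- 0
  for (i in seq_len(ncol(values))) {
    ch <- 0
    for (j in seq_len(nrow(values))) ch <- ch + values[j, i] / errors[j, i]
    acc <- acc + ch / nrow(values)
  }
  acc / ncol(values)
}

# Brute-force re-evaluation of the filter policy on one record.
brute_filter_flag <- function(r, policy) {
  vals <- unlist(r[intersect(policy$channels_minmax, names(r))],
                 use.names = FALSE)
  mu <- as.numeric(r[[policy$channel_sn]])
  sig <- as.numeric(r[[error_field(policy$channel_sn)]])
  sn <- mean(mu / sig)
  as.integer(min(vals) > policy$min_value &&
               max(vals) < policy$max_value && sn > policy$sn_threshold)
}

# Random prediction set shaped like `truth`.
jitter_set <- function(truth, sd) {
  lapply(truth, function(m) m + matrix(rnorm(length(m), 0, sd), nrow(m)))
}
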