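test_that("noiseless planted coefficients are recovered exactly at lambda 0", {
  cfg <- noiseless_config(n = 12, len = 50, scored = 40, window = 2, seed = 31)
  recs <- make_dataset(cfg)
  expect_warning(
    fit <- degscore(recs, channel = "deg_Mg_pH10", window = 2, lambda = 0),
    "minimum-norm")
  planted <- planted_model(cfg, "deg_Mg_pH10")
  expect_lt(max(abs(coef(fit) - coef(planted))), 1e-6)
  expect_lt(fit$training_rmse, 1e-10)
})

test_that("all-zero targets yield the zero model", {
  cfg <- noiseless_config(n = 4, seed = 32)
  recs <- make_dataset(cfg)
  recs <- lapply(recs, function(r) { r$reactivity <- rep(0, r$seq_scored); r })
  fit <- degscore(recs, channel = "reactivity", window = 2, lambda = 0.1)
  expect_lt(max(abs(coef(fit))), 1e-10)
})

test_that("extreme ridge shrinks slopes to zero and the intercept to the mean", {
  cfg <- tiny_config(n = 6, seed = 33)
  recs <- make_dataset(cfg)
  fit <- degscore(recs, channel = "deg_Mg_pH10", window = 2, lambda = 1e10)
  y <- unlist(lapply(recs, function(r) r$deg_Mg_pH10))
  expect_lt(max(abs(fit$coefficients)), 1e-5)
  expect_equal(fit$intercept, mean(y), tolerance = 1e-4)
})

test_that("the fit is invariant to the order of training records", {
  cfg <- tiny_config(n = 8, seed = 34)
  recs <- make_dataset(cfg)
  f1 <- degscore(recs, channel = "deg_Mg_50C", window = 2, lambda = 0.1)
  f2 <- degscore(rev(recs), channel = "deg_Mg_50C", window = 2, lambda = 0.1)
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-10)
})

test_that("coefficient noise shrinks as the dataset grows", {
  errs <- vapply(c(6, 24, 96), function(n) {
    cfg <- tiny_config(n = n, len = 50, scored = 40, window = 2, seed = 35,
                       latent_sd = 0,
                       motif_effects = c(triloop = 0, internal_symmetric = 0,
                                         internal_asymmetric = 0))
    recs <- make_dataset(cfg)
    fit <- degscore(recs, channel = "reactivity", window = 2, lambda = 1e-8)
    planted <- planted_model(cfg, "reactivity")
    sqrt(mean((coef(fit) - coef(planted))^2))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("the boosted variant captures nonlinearity the linear model cannot", {
  # interaction target (unpaired AND U) that no additive model can represent
  set.seed(36)
  seqs <- generate_sequences(12, length = 40, prefix = NULL)
  recs <- lapply(seq_along(seqs), function(i) {
    db <- sample_structure(seqs[[i]])
    cc <- strsplit(seqs[[i]], "")[[1]]
    paired <- strsplit(db, "")[[1]] != "."
    y <- as.numeric(cc == "U" & !paired)
    rna_record(names(seqs)[i], seqs[[i]], db, reactivity = y[1:40],
               reactivity_error = rep(0.1, 40), seq_scored = 40)
  })
  lin <- degscore(recs, channel = "reactivity", window = 0, lambda = 0.01)
  xgb <- degscore(recs, channel = "reactivity", window = 0, method = "xgb",
                  xgb_params = list(nrounds = 50, max_depth = 3, eta = 0.3),
                  seed = 1)
  expect_lt(xgb$training_rmse, lin$training_rmse)

  # constant target -> constant prediction
  recs_const <- lapply(recs, function(r) {
    r$reactivity <- rep(1.5, r$seq_scored); r
  })
  xgb_const <- degscore(recs_const, channel = "reactivity", window = 0,
                        method = "xgb",
                        xgb_params = list(nrounds = 20, max_depth = 2,
                                          eta = 0.3), seed = 1)
  p <- predict(xgb_const, recs_const[[1]])
  expect_lt(diff(range(p)), 1e-6)
  expect_equal(mean(p), 1.5, tolerance = 1e-3)
})

test_that("boosted training is deterministic given the seed and near ridge on linear signal", {
  cfg <- tiny_config(n = 10, seed = 37)
  recs <- make_dataset(cfg)
  xp <- list(nrounds = 60, max_depth = 4, eta = 0.2)
  f1 <- degscore(recs[1:8], channel = "deg_Mg_pH10", window = 2,
                 method = "xgb", xgb_params = xp, seed = 9)
  f2 <- degscore(recs[1:8], channel = "deg_Mg_pH10", window = 2,
                 method = "xgb", xgb_params = xp, seed = 9)
  held <- recs[9:10]
  p1 <- predict(f1, held); p2 <- predict(f2, held)
  expect_identical(p1, p2)

  ridge <- degscore(recs[1:8], channel = "deg_Mg_pH10", window = 2,
                    lambda = 0.1)
  rmse <- function(fit) {
    y <- unlist(lapply(held, function(r) r$deg_Mg_pH10))
    p <- unlist(lapply(predict(fit, held),
                       function(v) v[seq_len(held[[1]]$seq_scored)]))
    sqrt(mean((y - p)^2))
  }
  expect_lt(rmse(f1), 2 * rmse(ridge))
})

test_that("model accessors and printing expose the fit", {
  cfg <- tiny_config(n = 5, seed = 38)
  recs <- make_dataset(cfg)
  fit <- degscore(recs, channel = "reactivity", window = 2, lambda = 0.1)
  expect_length(fitted(fit), fit$n_obs)
  expect_equal(fitted(fit) + residuals(fit),
               unlist(lapply(recs, function(r) r$reactivity)),
               tolerance = 1e-12, ignore_attr = TRUE)
  tab <- coef_table(fit)
  expect_equal(nrow(tab), count_parameters(2) - 1L)
  expect_output(print(fit), "window w = 2")
  expect_output(print(summary(fit)), "largest-magnitude")
})
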