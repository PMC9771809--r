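test_that("MCRMSE matches hand evaluation and reduces to RMSE for one channel", {
  m <- cbind(reactivity = c(1, 2, 3, 4), deg_Mg_pH10 = c(0, 0, 0, 0))
  p <- m
  p[, 1] <- p[, 1] + 1          # residuals uniformly 1
  p[, 2] <- p[, 2] + 3          # residuals uniformly 3
  rep <- mcrmse(m, p)
  expect_equal(rep$mcrmse, 2.0)
  expect_equal(unname(rep$per_channel_rmse), c(1, 3))

  expect_equal(mcrmse(m, m)$mcrmse, 0)

  single <- m[, 1, drop = FALSE]
  expect_equal(mcrmse(single, single + 2)$mcrmse, 2)
})

test_that("MCRMSE pools positions across constructs and matches the loop oracle", {
  set.seed(51)
  truth <- lapply(1:5, function(i) {
    m <- matrix(rnorm(3 * 8), 8, 3,
                dimnames = list(NULL, c("reactivity", "deg_Mg_pH10",
                                        "deg_Mg_50C")))
    m
  })
  names(truth) <- paste0("c", 1:5)
  pred <- jitter_set(truth, 0.5)
  rep <- mcrmse(truth, pred)
  expect_equal(rep$mcrmse, loop_mcrmse(truth, pred), tolerance = 1e-12)
  expect_equal(rep$n_scored_nt, 5 * 8 * 3)

  # permutation within channels and linear scaling of residuals
  perm <- sample(5)
  expect_equal(mcrmse(truth[perm], pred[perm])$mcrmse, rep$mcrmse)
  pred2 <- lapply(names(truth), function(id) {
    truth[[id]] + 3 * (pred[[id]] - truth[[id]])
  })
  names(pred2) <- names(truth)
  expect_equal(mcrmse(truth, pred2)$mcrmse, 3 * rep$mcrmse, tolerance = 1e-12)
})

test_that("MCRMSE rejects empty masks and silent NaNs", {
  m <- cbind(reactivity = c(1, 2))
  expect_error(mcrmse(m, cbind(reactivity = rep(1, 3))), "shapes differ")
  p <- m; p[1] <- NaN
  expect_error(mcrmse(m, p), "missing values")
  expect_equal(mcrmse(m, p, na_skip = TRUE)$n_scored_nt, 1)
})

test_that("signal-to-noise ratio is the mean over channels of mean mu/sigma", {
  expect_equal(sn_ratio(matrix(2, 10, 3), matrix(1, 10, 3)), 2.0)
  mu <- matrix(runif(20, 0.5, 2), 10, 2)
  expect_equal(sn_ratio(mu, mu), 1.0)

  set.seed(52)
  mu <- matrix(rnorm(30, 2), 10, 3)
  sig <- matrix(runif(30, 0.1, 1), 10, 3)
  expect_equal(sn_ratio(mu, sig), loop_sn_ratio(mu, sig), tolerance = 1e-12)

  sig[3, 2] <- 0
  expect_error(sn_ratio(mu, sig), "sigma")
  manual <- mean(c(mean(mu[, 1] / sig[, 1]),
                   mean(mu[-3, 2] / sig[-3, 2]),
                   mean(mu[, 3] / sig[, 3])))
  expect_equal(sn_ratio(mu, sig, zero_sigma = "exclude"), manual,
               tolerance = 1e-12)
})

test_that("within-error agreement uses a strict inequality", {
  x <- c(1, 2, 3)
  expect_equal(within_error_fraction(x, x, rep(0.1, 3)), 1.0)
  expect_equal(within_error_fraction(x, x + 0.5, rep(0, 3)), 0.0)
  expect_equal(within_error_fraction(x, x, rep(0, 3)), 0.0)  # strict <
  expect_error(within_error_fraction(x, x, c(0.1, 0.1)), "lengths")
})

test_that("an error-free predictor agrees within one sigma at the Gaussian rate", {
  set.seed(53)
  n <- 1e5
  truth <- runif(n, 0.5, 3)
  sigma <- 0.05 + 0.15 * sqrt(truth)
  noisy <- truth + rnorm(n, 0, sigma)
  frac <- within_error_fraction(truth, noisy, sigma)
  expected <- 2 * pnorm(1) - 1            # erf(1/sqrt(2)) ~ 0.6827
  binom_sd <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * binom_sd)
})

test_that("motif aggregation pools by structural context", {
  vals <- list(rep(1, 9))
  tab <- motif_aggregate(vals, list("(((...)))"))
  expect_true(all(tab$mean == 1.0))

  db <- "(((...)))"
  v <- ifelse(strsplit(annotate_loop_types(db), "")[[1]] == "H", 2, 0)
  tab <- motif_aggregate(list(v), list(db))
  expect_equal(tab$mean[tab$motif == "triloop"], 2.0)
  expect_equal(tab$mean[tab$motif == "H"], 2.0)
  expect_equal(tab$mean[tab$motif == "S"], 0.0)
  expect_equal(tab$n[tab$motif == "triloop"], 3L)

  # symmetric internal loop vs bulge partition the flanking dots
  sym <- "(.((...)).)"
  bul <- "(.((...)))"
  tab2 <- motif_aggregate(list(rep(1, 11), rep(1, 10)), list(sym, bul))
  expect_equal(tab2$n[tab2$motif == "I"], 2L)
  expect_equal(tab2$n[tab2$motif == "B"], 1L)
  expect_equal(tab2$n[tab2$motif == "internal_symmetric"], 2L)
  expect_false("internal_asymmetric" %in% tab2$motif)

  asym <- "(..((...)).)"
  tab3 <- motif_aggregate(list(rep(1, 12)), list(asym))
  expect_equal(tab3$n[tab3$motif == "internal_asymmetric"], 3L)

  expect_error(motif_aggregate(vals, list("(((...)))"), rules = "nope"),
               "unknown motif rule")
})

test_that("rank correlation matches explicit rank computation, with ties", {
  x <- 1:10
  expect_equal(rank_correlation(x, x)$rho, 1.0)
  expect_equal(rank_correlation(x, -x)$rho, -1.0)
  expect_error(rank_correlation(x, rep(1, 10)), "constant")
  expect_error(rank_correlation(1:2, 2:1), "at least 3")

  set.seed(54)
  x <- sample(1:5, 20, replace = TRUE)   # heavy ties
  y <- x + rnorm(20)
  rho <- rank_correlation(x, y)$rho
  expect_equal(rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  p2 <- rank_correlation(x, y)$p_value
  expect_true(p2 > 0 && p2 < 1)
})
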