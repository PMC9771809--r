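test_that("sequence generation honours composition, prefix and determinism", {
  s <- generate_sequences(5, length = 30, gc_content = 0, prefix = NULL,
                          seed = 91)
  expect_false(any(grepl("[GC]", s)))

  s1 <- generate_sequences(10, length = 50, seed = 92)
  s2 <- generate_sequences(10, length = 50, seed = 92)
  expect_identical(s1, s2)
  expect_true(all(startsWith(s1, "GGAAA")))
  expect_true(all(nchar(s1) == 50))

  long <- generate_sequences(1, length = 1e4, gc_content = 0.5, prefix = NULL,
                             seed = 93)
  gc <- mean(strsplit(long, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e4))

  expect_error(generate_sequences(1, gc_content = 1.2), "gc_content")
})

test_that("sampled structures are valid, complementary and respect hairpin minima", {
  expect_equal(sample_structure(strrep("A", 30), seed = 94),
               strrep(".", 30))

  set.seed(95)
  for (i in 1:1000) {
    sq <- generate_sequences(1, length = 50, prefix = NULL)
    db <- sample_structure(sq)
    pt <- parse_dotbracket(db)           # round-trips the parser
    p <- pt$partner
    paired <- which(!is.na(p) & p > seq_along(p))
    if (length(paired)) {
      cc <- strsplit(sq, "")[[1]]
      legal <- c("AU", "UA", "GC", "CG", "GU", "UG")
      expect_true(all(paste0(cc[paired], cc[p[paired]]) %in% legal))
      # innermost pairs enclose a hairpin loop of >= 3 nt
      gaps <- p[paired] - paired - 1L
      inner <- vapply(seq_along(paired), function(k) {
        span <- (paired[k] + 1L):(p[paired[k]] - 1L)
        all(is.na(p[span])) # hairpin-closing pair
      }, NA)
      expect_true(all(gaps[inner] >= 3))
    }
  }
})

test_that("planted measurements reduce to the linear model in the noiseless limit", {
  cfg <- noiseless_config(n = 1, len = 40, scored = 30, window = 2, seed = 96)
  sq <- generate_sequences(1, length = 40, seed = 96)[[1]]
  db <- sample_structure(sq, seed = 97)
  pm <- plant_measurements(sq, db, cfg)
  model <- planted_model(cfg, cfg$channels[2])
  expect_equal(unname(pm$values[, 2]),
               predict(model, list(sequence = sq, structure = db))[1:30],
               tolerance = 1e-12)
  expect_true(all(pm$errors == 0))

  # motif offsets shift the truth additively
  cfg2 <- tiny_config(n = 1, len = 40, scored = 30, window = 2, seed = 96,
                      noise_floor = 0, noise_scale = 0, latent_sd = 0,
                      motif_effects = c(triloop = 0.6,
                                        internal_symmetric = 0.1,
                                        internal_asymmetric = 0.3))
  pm2 <- plant_measurements(sq, db, cfg2)
  ann <- strsplit(annotate_loop_types(db), "")[[1]]
  shifted <- pm2$truth[, 2] - pm$truth[, 2]
  expect_true(all(shifted[ann == "S"] == 0))
})

test_that("noisy planted data have calibrated errors and SN falls with noise", {
  cfg <- tiny_config(n = 1, len = 2000, scored = 2000, window = 1, seed = 98,
                     latent_sd = 0)
  sq <- generate_sequences(1, length = 2000, seed = 98)[[1]]
  db <- strrep(".", 2000)
  pm <- plant_measurements(sq, db, cfg, seed = 99)
  frac <- within_error_fraction(pm$truth[, 1], pm$values[, 1], pm$errors[, 1])
  expect_lt(abs(frac - 0.6827), 0.035)

  sns <- vapply(c(0.6, 0.15, 0.02), function(b) {
    cfgb <- tiny_config(n = 1, len = 300, scored = 300, window = 1, seed = 98,
                        noise_scale = b, latent_sd = 0)
    pmb <- plant_measurements(sq2 <- generate_sequences(
      1, length = 300, seed = 100)[[1]],
      strrep(".", 300), cfgb, seed = 101)
    sn_ratio(pmb$values, pmb$errors)
  }, 0)
  expect_true(all(diff(sns) > 0))
})

test_that("datasets round-trip through serialization and honour injection rates", {
  cfg <- tiny_config(n = 10, seed = 102)
  recs <- make_dataset(cfg)
  D <- rnadeg:::sequence_distance_matrix(
    stats::setNames(vapply(recs, function(r) r$sequence, ""),
                    vapply(recs, function(r) r$id, "")))
  expect_gt(min(D[upper.tri(D)]), 0)   # duplicate rate 0 -> all distinct

  path <- tempfile(fileext = ".json")
  write_rna_records(recs, path)
  back <- read_rna_records(path)
  expect_equal(length(back), 10)
  expect_equal(back[[3]]$sequence, recs[[3]]$sequence)
  expect_equal(back[[3]]$deg_Mg_pH10, recs[[3]]$deg_Mg_pH10,
               tolerance = 1e-12)
  expect_equal(back[[3]]$SN_filter, recs[[3]]$SN_filter)

  cfg_dup <- tiny_config(n = 20, seed = 103, duplicate_rate = 0.25)
  recs_dup <- make_dataset(cfg_dup)
  D2 <- rnadeg:::sequence_distance_matrix(
    stats::setNames(vapply(recs_dup, function(r) r$sequence, ""),
                    vapply(recs_dup, function(r) r$id, "")))
  near <- sum(D2[upper.tri(D2)] < 0.1)
  expect_gte(near, 5)                  # injected near-duplicates present
})

test_that("the planted filter-failure fraction is recovered by the SN filter", {
  cfg <- tiny_config(n = 100, seed = 104, fail_fraction = 0.2)
  recs <- make_dataset(cfg)
  flags <- vapply(recs, function(r) r$SN_filter, 0L)
  expect_gte(sum(flags == 0L), 20)     # all injected failures flagged
  expect_lte(sum(flags == 0L), 30)     # plus at most a few organic ones
})
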