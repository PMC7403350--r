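test_that("identical configs give identical tensors; different seeds differ", {
  base <- fx_base_set()
  cfg <- sim_config(n_sites = 10, n_reps = 3, seed = 21)
  t1 <- simulate_population(base, cfg)
  t2 <- simulate_population(base, cfg)
  expect_identical(t1$rates, t2$rates)
  t3 <- simulate_population(base, sim_config(n_sites = 10, n_reps = 3, seed = 22))
  expect_false(identical(t1$rates, t3$rates))
})

test_that("without conjunctive terms a string's expected rate is the sum of its
           letter-at-slot rates minus three baselines", {
  base <- build_base_set(n_words = 4, n_pseudo = 4, seed = 2,
                         config = fx_config())
  lets <- fx_letter_set()
  all <- c_stimulus_sets(base, lets)
  cfg <- sim_config(n_sites = 8, n_reps = 2, nonlinearity_weight = 0,
                    frac_word_selective = 0, variation_jitter_sd = 0,
                    seed = 5)
  tens <- simulate_population(all, cfg)
  mu <- tens$truth$expected_rate
  m <- tens$stim_meta
  si <- which(m$lexical_class == "word" & m$font_case == "upper" &
                m$font_size == "medium")[1]
  ltr <- strsplit(m$text[si], "")[[1]]
  letter_cols <- vapply(1:4, function(k)
    which(m$text == ltr[k] & m$position_slot == k &
            m$font_case == "upper" & m$font_size == "medium"), 0L)
  expect_equal(mu[, si], rowSums(mu[, letter_cols]) - 3 * cfg$baseline_rate,
               tolerance = 1e-10)
})

test_that("planted word-selective sites realize their target d' range", {
  base <- build_base_set(n_words = 60, n_pseudo = 60, seed = 4,
                         config = fx_config())
  cfg <- sim_config(n_sites = 60, n_reps = 12, seed = 13)
  tens <- simulate_population(base, cfg)
  m <- tens$stim_meta
  canon <- m$font_case == "upper" & m$font_size == "medium"
  resp <- average_repetitions(tens, "early_only")$matrix[, canon]
  labs <- m$lexical_class[canon] == "word"
  d <- apply(resp, 1, function(r) selectivity_dprime(r[labs], r[!labs]))
  pl <- tens$truth$selective_sites
  expect_length(pl, 6)  # 10% of 60
  # mean realized |d'| of planted sites within the configured range, up to
  # Monte-Carlo error; individual sites track their targets
  expect_gt(mean(abs(d[pl])), 0.15 - 0.1)
  expect_lt(mean(abs(d[pl])), 0.45 + 0.1)
  expect_gt(stats::cor(d[pl], tens$truth$target_dprime[pl]), 0.7)
  expect_lt(max(abs(d[pl])), 0.85)
  # non-selective sites centre on zero
  expect_lt(abs(mean(d[-pl])), 0.1)
})

test_that("fully mirror-symmetric populations respond equally to mirror letters", {
  lets <- fx_letter_set()
  cfg <- sim_config(n_sites = 12, n_reps = 2, mirror_symmetric_fraction = 1,
                    variation_jitter_sd = 0, seed = 3)
  tens <- simulate_population(lets, cfg)
  mu <- tens$truth$expected_rate
  m <- tens$stim_meta
  for (pair in list(c("B", "D"), c("P", "Q"))) {
    i1 <- which(m$text == pair[1] & m$position_slot == 2 &
                  m$font_case == "lower" & m$font_size == "medium")
    i2 <- which(m$text == pair[2] & m$position_slot == 2 &
                  m$font_case == "lower" & m$font_size == "medium")
    expect_equal(mu[, i1], mu[, i2], tolerance = 1e-10)
  }
})

test_that("split-half letter reliability grows with repetitions", {
  lets <- build_letter_set(variations = 1, config = fx_config())
  rel_at <- function(nr) {
    tens <- simulate_population(lets, sim_config(n_sites = 25, n_reps = nr,
                                                 seed = 31))
    mean(screen_letter_reliability(tens, seed = 5)$split_half_r)
  }
  rs <- vapply(c(2, 8, 32), rel_at, 0)
  expect_true(all(diff(rs) > 0))
})

test_that("reference behavior links errors to bigram frequency", {
  base <- fx_base_set()
  ct <- simulate_reference_behavior(base, n_subjects = 1, trials_per_stim = 60,
                                    freq_slope = 1, seed = 8)
  pw <- ct[ct$lexical_class == "pseudoword", ]
  stim <- unique(pw[, c("stimulus_id", "mean_bigram_freq")])
  q <- cut(stim$mean_bigram_freq, quantile(stim$mean_bigram_freq, 0:4 / 4),
           include.lowest = TRUE, labels = FALSE)
  far <- vapply(1:4, function(b) {
    ids <- stim$stimulus_id[q == b]
    mean(pw$choice[pw$stimulus_id %in% ids] == "word")
  }, 0)
  expect_true(all(diff(far) > -0.02))   # monotone non-decreasing up to noise
  expect_gt(far[4], far[1])

  # flat generative model: per-bin d' roughly constant
  ct0 <- simulate_reference_behavior(base, n_subjects = 1, lapse = 0,
                                     trials_per_stim = 200, freq_slope = 0,
                                     seed = 9)
  sig0 <- binned_signature(ct0, n_bins = 5)
  expect_lt(diff(range(sig0$dprime_per_bin)), 0.8)

  # identical generative processes converge to the same signature
  ct2 <- simulate_reference_behavior(base, n_subjects = 2,
                                     trials_per_stim = 400, seed = 10)
  s1 <- binned_signature(ct2[ct2$subject_id == "subject_1", ], n_bins = 5)
  s2 <- binned_signature(ct2[ct2$subject_id == "subject_2", ], n_bins = 5)
  expect_gt(stats::cor(s1$dprime_per_bin, s2$dprime_per_bin), 0.9)

  expect_error(simulate_reference_behavior(fx_letter_set()), "no string")
})

test_that("tensor containers round-trip losslessly and police their schema", {
  base <- build_base_set(n_words = 2, n_pseudo = 2, seed = 2,
                         config = fx_config())
  tens <- simulate_population(base, sim_config(n_sites = 3, n_reps = 2,
                                               seed = 17))
  path <- file.path(tempdir(), "tensor_rt")
  unlink(path, recursive = TRUE)
  write_tensor(tens, path)
  back <- read_tensor(path)
  expect_identical(as.numeric(back$rates), as.numeric(tens$rates))
  expect_identical(as.numeric(back$baseline), as.numeric(tens$baseline))
  expect_identical(back$stimulus_ids, tens$stimulus_ids)
  expect_identical(back$window_labels, tens$window_labels)

  # an older 1.x container still reads
  hp <- file.path(path, "header.json")
  h <- jsonlite::fromJSON(readLines(hp))
  h$schema_version <- "1.0"
  writeLines(jsonlite::toJSON(h, auto_unbox = TRUE), hp)
  expect_s3_class(read_tensor(path), "response_tensor")

  # missing window labels are rejected
  h$window_labels <- NULL
  writeLines(jsonlite::toJSON(h, auto_unbox = TRUE), hp)
  expect_error(read_tensor(path), "window")

  # unsupported major version is rejected
  h$window_labels <- tens$window_labels
  h$schema_version <- "2.0"
  writeLines(jsonlite::toJSON(h, auto_unbox = TRUE), hp)
  expect_error(read_tensor(path), "version")
})
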