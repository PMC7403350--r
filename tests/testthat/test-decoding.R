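test_that("the default battery has 30 tasks with sane class structure", {
  base <- build_base_set(n_words = 60, n_pseudo = 60, seed = 3,
                         config = fx_config())
  inv <- subsample_invariant_set(base, n_words = 40, n_pseudo = 40,
                                 n_variations = 5, seed = 2)
  battery <- build_task_battery(base, inv)
  expect_length(battery, 30)
  fams <- vapply(battery, `[[`, "", "family")
  expect_equal(sum(fams == "letter_id"), 20)
  expect_equal(sum(fams == "bigram_id"), 8)
  for (t in battery) {
    expect_gt(length(t$positive_ids), 0)
    expect_gt(length(t$negative_ids), 0)
    expect_length(intersect(t$positive_ids, t$negative_ids), 0)
  }
  # letter tasks non-degenerate, and the most balanced tokens were preferred:
  # every chosen token is at least as balanced as every unchosen one
  lt <- battery[fams == "letter_id"]
  prop <- vapply(lt, function(t)
    length(t$positive_ids) / (length(t$positive_ids) + length(t$negative_ids)),
    0)
  expect_true(all(prop > 0 & prop < 1))
  chosen <- vapply(lt, `[[`, "", "token")
  texts <- inv$meta$text
  all_prop <- vapply(LETTERS, function(tk) mean(grepl(tk, texts, fixed = TRUE)), 0)
  unchosen <- setdiff(LETTERS[all_prop > 0 & all_prop < 1], chosen)
  if (length(unchosen) > 0)
    expect_lte(max(abs(prop - 0.5)), min(abs(all_prop[unchosen] - 0.5)))

  expect_length(build_task_battery(base, inv, n_letter_tasks = 0,
                                   n_bigram_tasks = 0), 2)
  fx$big_base <- base; fx$big_inv <- inv  # reused below
})

test_that("invariant subsample has (n_words+n_pseudo) x n_variations stimuli", {
  base <- fx_base_set()
  inv <- subsample_invariant_set(base, n_words = 10, n_pseudo = 10,
                                 n_variations = 5, seed = 4)
  expect_equal(nrow(inv$meta), 100)
  expect_equal(nrow(subsample_invariant_set(base, 1, 1, 1, seed = 1)$meta), 2)
  expect_identical(subsample_invariant_set(base, 5, 5, 3, seed = 9)$meta,
                   subsample_invariant_set(base, 5, 5, 3, seed = 9)$meta)
  expect_error(subsample_invariant_set(base, n_words = 500), "too small")
})

.toy_task <- function(n_pos = 30, n_neg = 30) {
  list(task_id = "toy", family = "letter_id", token = "A",
       positive_ids = sprintf("p%02d", seq_len(n_pos)),
       negative_ids = sprintf("n%02d", seq_len(n_neg)))
}

.toy_features <- function(task, n_feat = 20, sep = 2, seed = 1) {
  set.seed(seed)
  ids <- c(task$positive_ids, task$negative_ids)
  lab <- rep(c(1, 0), c(length(task$positive_ids), length(task$negative_ids)))
  x <- matrix(rnorm(n_feat * length(ids)), n_feat,
              dimnames = list(sprintf("site_%02d", seq_len(n_feat)), ids))
  x[1:5, ] <- x[1:5, ] + sep * rep(lab, each = 5)
  x
}

test_that("cross-validated decoding is correct on separable data and at chance
           on permuted labels", {
  task <- .toy_task()
  x <- .toy_features(task, sep = 4)
  d <- crossval_decode(x, task, seed = 3)
  expect_equal(d$accuracy, 1)
  expect_true(all(d$probabilities >= 0 & d$probabilities <= 1))
  # every stimulus tested exactly once per fold scheme
  expect_equal(as.integer(sort(table(d$fold))), rep(6L, 10))
  expect_equal(rownames(d$probabilities), d$stimulus_ids)

  # label permutation: accuracy near 0.5 over repetitions
  accs <- vapply(1:10, function(i) {
    set.seed(800 + i)
    xp <- x[, sample(ncol(x))]
    colnames(xp) <- colnames(x)
    crossval_decode(xp, task, seed = i)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.08)

  # reproducibility: same seed, same output
  expect_identical(crossval_decode(x, task, seed = 3)$probabilities,
                   d$probabilities)
})

test_that("duplicating every site leaves pooled accuracy unchanged", {
  task <- .toy_task()
  x <- .toy_features(task, sep = 0.7, seed = 5)
  x2 <- rbind(x, x)
  rownames(x2) <- c(rownames(x), paste0(rownames(x), "_dup"))
  a1 <- crossval_decode(x, task, seed = 2)$accuracy
  a2 <- crossval_decode(x2, task, seed = 2)$accuracy
  expect_lt(abs(a1 - a2), 0.1)
})

test_that("site-count sweeps are degenerate-consistent and signal-monotone", {
  task <- .toy_task(40, 40)
  x <- .toy_features(task, n_feat = 30, sep = 0.6, seed = 7)
  sw <- site_count_sweep(x, task, site_counts = c(30), n_site_samples = 1,
                         seed = 4)
  pooled <- crossval_decode(x, task, seed = 4)$accuracy
  expect_equal(sw$accuracy_mean, pooled)

  sw2 <- site_count_sweep(x, task, site_counts = c(3, 30),
                          n_site_samples = 8, seed = 6)
  expect_lte(sw2$accuracy_mean[1],
             sw2$accuracy_mean[2] + 2 * sw2$accuracy_sd[1])

  # zero signal: flat chance curve
  x0 <- .toy_features(task, n_feat = 30, sep = 0, seed = 8)
  sw0 <- site_count_sweep(x0, task, site_counts = c(5, 30),
                          n_site_samples = 8, seed = 9)
  expect_true(all(abs(sw0$accuracy_mean - 0.5) < 0.12))
  expect_error(site_count_sweep(x, task, site_counts = 99), "exceeds")
})

test_that("external feature matrices go through the identical machinery", {
  task <- .toy_task()
  x <- .toy_features(task, sep = 3, seed = 9)
  out <- decode_external_features(x, list(task), seed = 5)
  expect_named(out, "toy")
  expect_equal(out$toy$accuracy, crossval_decode(x, task, seed = 5)$accuracy)
  # same seed implies the same fold plan for any feature matrix
  x2 <- .toy_features(task, sep = 0.5, seed = 10)
  expect_identical(out$toy$fold, crossval_decode(x2, task, seed = 5)$fold)
  # misaligned stimulus ids are rejected
  bad <- x; colnames(bad)[1] <- "nope"
  expect_error(crossval_decode(bad, task, seed = 1), "missing")
})

test_that("decoder choice tables feed the consistency machinery", {
  base <- fx_base_set()
  tens <- fx_tensor()
  f <- average_repetitions(tens, "both_concatenated")
  inv <- subsample_invariant_set(base, n_words = 10, n_pseudo = 10,
                                 n_variations = 5, seed = 2)
  wc <- build_task_battery(base, inv, n_letter_tasks = 0,
                           n_bigram_tasks = 0)[[1]]
  canon <- base$meta[base$meta$font_case == "upper" &
                       base$meta$font_size == "medium", ]
  tab <- decoder_choice_table(f, wc, canon, n_repeats = 4, seed = 3)
  expect_equal(nrow(tab), 4 * nrow(canon))
  expect_true(all(tab$choice %in% c("word", "pseudoword")))
  expect_true(all(table(tab$stimulus_id) == 4))
})
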