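.ORTHO_RIDGE_LAMBDA <- 0.05      # binary readout L2 strength, frozen after one-off nested validation
.ORTHO_MULTINOM_LAMBDA <- 5      # 26-way letter decoder L2 strength, frozen the same way

.as_features <- function(features) {
  if (inherits(features, "population_features")) return(features)
  if (is.matrix(features)) {
    ids <- colnames(features)
    if (is.null(ids)) stop("feature matrix needs stimulus ids as column names")
    sid <- rownames(features)
    if (is.null(sid)) sid <- sprintf("feat_%04d", seq_len(nrow(features)))
    return(structure(list(matrix = features, site_ids = sid,
                          stimulus_ids = ids),
                     class = "population_features"))
  }
  stop("features must be a population_features object or a matrix")
}

#' Build the orthographic task battery
#'
#' Assembles the default 30-task battery: \code{n_letter_tasks} invariant
#' letter-identification tasks and \code{n_bigram_tasks} invariant
#' bigram-identification tasks (binary "token present anywhere in the
#' string" discriminations over the invariant variation set), plus two word
#' classification variants — (i) the base set restricted to canonical views
#' (upper case, medium size) and (ii) the invariant subsampled set.  Tokens
#' are picked deterministically as those with the most label-balanced
#' positive/negative splits (ties alphabetical); pass a seed to randomize
#' among near-balanced tokens instead.
#'
#' @param base_set the base string \code{stimulus_set}.
#' @param invariant_set an invariant subset, see [subsample_invariant_set()];
#'   built from \code{base_set} with defaults when NULL.
#' @param n_letter_tasks,n_bigram_tasks task counts (defaults 20 and 8).
#' @param seed optional; when given, token choice samples among the 2x
#'   most-balanced candidates instead of the deterministic pick.
#' @return A list of task specs (task_id, family, positive_ids,
#'   negative_ids, token), of length n_letter_tasks + n_bigram_tasks + 2.
#' @export
build_task_battery <- function(base_set, invariant_set = NULL,
                               n_letter_tasks = 20, n_bigram_tasks = 8,
                               seed = NULL) {
  if (is.null(invariant_set))
    invariant_set <- subsample_invariant_set(base_set)
  im <- invariant_set$meta
  texts <- im$text
  balance_pick <- function(tokens, contains, n_pick) {
    prop <- vapply(tokens, function(tk) mean(contains(tk)), 0)
    ok <- tokens[prop > 0 & prop < 1]
    if (length(ok) < n_pick)
      stop("only ", length(ok), " tokens with non-degenerate splits; ",
           n_pick, " requested")
    score <- abs(prop[ok] - 0.5)
    ord <- order(score, ok)
    if (is.null(seed)) return(ok[ord][seq_len(n_pick)])
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    pool <- ok[ord][seq_len(min(length(ok), 2 * n_pick))]
    sample(pool, n_pick)
  }
  tasks <- list()
  if (n_letter_tasks > 0) {
    lt <- balance_pick(LETTERS, function(tk) grepl(tk, texts, fixed = TRUE),
                       n_letter_tasks)
    for (tk in lt) {
      pos <- im$stimulus_id[grepl(tk, texts, fixed = TRUE)]
      tasks[[length(tasks) + 1]] <- list(
        task_id = paste0("letter_", tk), family = "letter_id", token = tk,
        positive_ids = pos, negative_ids = setdiff(im$stimulus_id, pos))
    }
  }
  if (n_bigram_tasks > 0) {
    bgs <- sort(unique(unlist(lapply(unique(texts), function(s)
      vapply(1:3, function(i) substr(s, i, i + 1), "")))))
    bt <- balance_pick(bgs, function(tk) grepl(tk, texts, fixed = TRUE),
                       n_bigram_tasks)
    for (tk in bt) {
      pos <- im$stimulus_id[grepl(tk, texts, fixed = TRUE)]
      tasks[[length(tasks) + 1]] <- list(
        task_id = paste0("bigram_", tk), family = "bigram_id", token = tk,
        positive_ids = pos, negative_ids = setdiff(im$stimulus_id, pos))
    }
  }
  bm <- base_set$meta
  canon <- bm$font_case == "upper" & bm$font_size == "medium" &
    bm$lexical_class %in% c("word", "pseudoword")
  tasks[[length(tasks) + 1]] <- list(
    task_id = "word_classification_base", family = "word_classification",
    token = NA_character_,
    positive_ids = bm$stimulus_id[canon & bm$lexical_class == "word"],
    negative_ids = bm$stimulus_id[canon & bm$lexical_class == "pseudoword"])
  tasks[[length(tasks) + 1]] <- list(
    task_id = "word_classification_invariant",
    family = "word_classification_invariant", token = NA_character_,
    positive_ids = im$stimulus_id[im$lexical_class == "word"],
    negative_ids = im$stimulus_id[im$lexical_class == "pseudoword"])
  for (t in tasks)
    if (length(t$positive_ids) == 0 || length(t$negative_ids) == 0 ||
        length(intersect(t$positive_ids, t$negative_ids)) > 0)
      stop("degenerate task: ", t$task_id)
  tasks
}

#' Subsample the invariant stimulus set
#'
#' Draws \code{n_words} words and \code{n_pseudo} pseudowords from the base
#' set and keeps \code{n_variations} of the six case/size variations for
#' each (the same variations for every string), giving
#' \code{(n_words + n_pseudo) * n_variations} stimuli — 400 with defaults.
#'
#' @param base_set base string \code{stimulus_set}.
#' @param n_words,n_pseudo,n_variations sampling sizes (40, 40, 5).
#' @param seed integer seed.
#' @return A \code{stimulus_set}.
#' @export
subsample_invariant_set <- function(base_set, n_words = 40, n_pseudo = 40,
                                    n_variations = 5, seed = 1) {
  m <- base_set$meta
  words <- unique(m$text[m$lexical_class == "word"])
  pseudos <- unique(m$text[m$lexical_class == "pseudoword"])
  if (length(words) < n_words || length(pseudos) < n_pseudo)
    stop("base set too small for requested invariant subsample")
  stopifnot(n_variations >= 1, n_variations <= 6)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tw <- sample(words, n_words); tp <- sample(pseudos, n_pseudo)
  vars <- unique(m[, c("font_case", "font_size")])
  keepv <- vars[sample.int(nrow(vars), n_variations), , drop = FALSE]
  keep <- m$text %in% c(tw, tp) &
    paste(m$font_case, m$font_size) %in% paste(keepv$font_case, keepv$font_size)
  .new_stimulus_set(base_set$images[keep], m[keep, , drop = FALSE])
}

.stratified_folds <- function(labels, n_folds) {
  # labels: logical; returns integer fold per element, classes balanced
  fold <- integer(length(labels))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds)
      stop("class with ", length(idx), " stimuli cannot fill ", n_folds, " folds")
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

.fit_predict_logistic <- function(xtr, ytr, xte, lambda) {
  # per-feature standardization from training folds only
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2, stats::sd); sg[sg == 0] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
  fit <- glmnet::glmnet(xtr, factor(ytr, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  as.numeric(stats::predict(fit, xte, type = "response"))
}

#' Cross-validated linear decoding of one task
#'
#' Binary logistic (ridge-regularized) readout with stratified ten-fold
#' cross-validation: weights are learned on 90\% of stimuli and class
#' probabilities produced for the held-out 10\%, so every stimulus is tested
#' exactly once per fold scheme.  The whole procedure is repeated over
#' independent random samples of neural sites.  The hard choice is
#' probability > 0.5 (exactly 0.5 resolves to the negative class);
#' performance is balanced accuracy.
#'
#' @param features a \code{population_features} (or matrix with stimulus-id
#'   column names) covering all task stimuli.
#' @param task a task spec from [build_task_battery()].
#' @param n_folds folds (default 10).
#' @param n_site_samples random site samples (default 10).
#' @param sites_per_sample sites per sample; NULL uses all sites once.
#' @param seed integer seed controlling folds and site samples.
#' @param lambda ridge penalty (frozen package default).
#' @return A list of class \code{decode_output}: \code{accuracy} (mean
#'   balanced accuracy over samples), \code{accuracy_sd}, \code{per_sample},
#'   \code{probabilities} (stimulus x sample matrix of word/positive-class
#'   probabilities), \code{labels}, \code{stimulus_ids}, \code{fold}.
#' @export
crossval_decode <- function(features, task, n_folds = 10, n_site_samples = 10,
                            sites_per_sample = NULL, seed = 1,
                            lambda = .ORTHO_RIDGE_LAMBDA) {
  f <- .as_features(features)
  ids <- c(task$positive_ids, task$negative_ids)
  miss <- setdiff(ids, f$stimulus_ids)
  if (length(miss) > 0)
    stop("features missing ", length(miss), " task stimuli (e.g. ", miss[1], ")")
  col <- match(ids, f$stimulus_ids)
  labels <- c(rep(TRUE, length(task$positive_ids)),
              rep(FALSE, length(task$negative_ids)))
  x_all <- t(f$matrix[, col, drop = FALSE])  # stimuli x features
  usite <- unique(f$site_ids)
  if (!is.null(sites_per_sample) && sites_per_sample > length(usite))
    stop("sites_per_sample exceeds available sites")
  one_sample_only <- is.null(sites_per_sample)
  ns_samples <- if (one_sample_only) 1 else n_site_samples

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- .stratified_folds(labels, n_folds)
  probs <- matrix(NA_real_, length(ids), ns_samples,
                  dimnames = list(ids, NULL))
  acc <- numeric(ns_samples)
  for (smp in seq_len(ns_samples)) {
    keep_sites <- if (one_sample_only) usite else
      sample(usite, sites_per_sample)
    fcols <- f$site_ids %in% keep_sites
    x <- x_all[, fcols, drop = FALSE]
    if (ncol(x) == 1) x <- cbind(x, 0)  # glmnet needs >= 2 predictors
    p <- numeric(length(ids))
    for (k in seq_len(n_folds)) {
      te <- fold == k
      if (length(unique(labels[!te])) < 2) stop("training fold with one class")
      p[te] <- .fit_predict_logistic(x[!te, , drop = FALSE], labels[!te],
                                     x[te, , drop = FALSE], lambda)
    }
    probs[, smp] <- p
    acc[smp] <- balanced_accuracy(p > 0.5, labels)
  }
  structure(list(task_id = task$task_id, accuracy = mean(acc),
                 accuracy_sd = stats::sd(acc), per_sample = acc,
                 probabilities = probs, labels = labels,
                 stimulus_ids = ids, fold = fold,
                 n_folds = n_folds, seed = seed),
            class = "decode_output")
}

#' @export
print.decode_output <- function(x, ...) {
  cat(sprintf("decode_output [%s]: balanced accuracy %.3f (SD %.3f, n=%d samples)\n",
              x$task_id, x$accuracy,
              ifelse(is.na(x$accuracy_sd), 0, x$accuracy_sd),
              length(x$per_sample)))
  invisible(x)
}

#' Decoding accuracy as a function of site count
#'
#' Repeats [crossval_decode()] for each requested number of sites, with
#' independent random site samples, and summarizes mean and SD of balanced
#' accuracy per count.
#'
#' @inheritParams crossval_decode
#' @param site_counts integer vector of site counts to sweep.
#' @param n_site_samples samples per count (default 100).
#' @return A data.frame: n_sites, accuracy_mean, accuracy_sd.
#' @export
site_count_sweep <- function(features, task, site_counts,
                             n_site_samples = 100, n_folds = 10, seed = 1,
                             lambda = .ORTHO_RIDGE_LAMBDA) {
  f <- .as_features(features)
  if (max(site_counts) > length(unique(f$site_ids)))
    stop("site count exceeds available sites")
  out <- lapply(seq_along(site_counts), function(i) {
    d <- crossval_decode(f, task, n_folds = n_folds,
                         n_site_samples = n_site_samples,
                         sites_per_sample = site_counts[i],
                         seed = seed + i - 1, lambda = lambda)
    data.frame(n_sites = site_counts[i], accuracy_mean = d$accuracy,
               accuracy_sd = d$accuracy_sd)
  })
  do.call(rbind, out)
}

#' Run a task battery on externally supplied features
#'
#' Applies the identical cross-validated battery machinery to an arbitrary
#' stimulus-by-feature representation (e.g. pixels or units of an artificial
#' network), after verifying stimulus-id alignment.  With the same seed the
#' fold plan matches the one used for neural features.
#'
#' @param feature_matrix features x stimuli matrix with stimulus ids as
#'   column names (or a \code{population_features}).
#' @param tasks list of task specs.
#' @param ... passed to [crossval_decode()].
#' @return Named list of \code{decode_output}, one per task.
#' @export
decode_external_features <- function(feature_matrix, tasks, ...) {
  f <- .as_features(feature_matrix)
  out <- lapply(tasks, function(t) crossval_decode(f, t, ...))
  stats::setNames(out, vapply(tasks, `[[`, "", "task_id"))
}

#' Decoder choice table for consistency analyses
#'
#' Produces behavioral-style trials from a decoder: the word-classification
#' cross-validation is repeated \code{n_repeats} times with different fold
#' seeds, and each repeat's held-out hard choices form one "trial" per
#' stimulus.  Fold resampling restores trial-like variability for split-half
#' reliability, since the decoder is deterministic given a fold plan.
#'
#' @param features a \code{population_features}.
#' @param task a word-classification task spec.
#' @param stim_meta stimulus metadata (for lexical class and bigram
#'   frequency columns).
#' @param n_repeats number of repeats / pseudo-trials (default 10).
#' @param subject_id label for the decoder rows.
#' @param ... passed to [crossval_decode()] (e.g. sites_per_sample).
#' @param seed base seed; repeat r uses seed + r.
#' @return A choice table compatible with [consistency()].
#' @export
decoder_choice_table <- function(features, task, stim_meta, n_repeats = 10,
                                 subject_id = "decoder", seed = 1, ...) {
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    d <- crossval_decode(features, task, seed = seed + r, ...)
    pw <- rowMeans(d$probabilities)
    mrow <- match(d$stimulus_ids, stim_meta$stimulus_id)
    out[[r]] <- data.frame(
      subject_id = subject_id, stimulus_id = d$stimulus_ids,
      trial_index = r,
      choice = ifelse(pw > 0.5, "word", "pseudoword"),
      lexical_class = stim_meta$lexical_class[mrow],
      mean_bigram_freq = stim_meta$mean_bigram_freq[mrow],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
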