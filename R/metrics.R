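#' Balanced accuracy
#'
#' Unbiased binary performance \eqn{(HR + (1 - FAR))/2}, where HR is the
#' hit rate on the positive class and FAR the false-alarm rate on the
#' negative class.  Invariant to class imbalance.
#'
#' @param choices logical or 0/1 vector of positive-class choices.
#' @param labels logical or 0/1 vector of true positive-class labels.
#' @return Balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(choices, labels) {
  choices <- as.logical(choices); labels <- as.logical(labels)
  stopifnot(length(choices) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  hr <- mean(choices[labels])
  far <- mean(choices[!labels])
  (hr + (1 - far)) / 2
}

#' Sensitivity index d' from hit and false-alarm rates
#'
#' \eqn{d' = Z(HR) - Z(FAR)} with Z the standard-normal quantile function.
#' Extreme rates (0 or 1) are clipped to \eqn{[1/(2N), 1 - 1/(2N)]} using the
#' per-rate trial counts, the standard log-linear correction that keeps d'
#' finite.
#'
#' @param HR,FAR hit and false-alarm rates in [0, 1].
#' @param n_hit,n_fa trial counts behind each rate (used only for clipping;
#'   default 100).
#' @return d' (unitless).
#' @export
dprime <- function(HR, FAR, n_hit = 100, n_fa = 100) {
  stopifnot(HR >= 0, HR <= 1, FAR >= 0, FAR <= 1)
  clip <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(HR, n_hit)) - stats::qnorm(clip(FAR, n_fa))
}

.assign_freq_bins <- function(meta, n_bins) {
  # rank-matched quantile bins by mean bigram frequency, separately within
  # words and pseudowords; bin i pairs word-decile i with pseudoword-decile i
  bin <- integer(nrow(meta))
  for (cls in c("word", "pseudoword")) {
    idx <- which(meta$lexical_class == cls)
    if (length(idx) < n_bins)
      stop("too few ", cls, " stimuli (", length(idx), ") for ", n_bins, " bins")
    r <- rank(meta$mean_bigram_freq[idx], ties.method = "first")
    bin[idx] <- ceiling(n_bins * r / length(idx))
  }
  bin
}

#' Binned behavioral signature
#'
#' Groups string stimuli into \code{n_bins} equal-sized bins by mean bigram
#' frequency, separately for words and pseudowords (bin i pairs word
#' quantile-bin i with pseudoword quantile-bin i), and computes the per-bin
#' sensitivity \eqn{d' = Z(HR_i) - Z(FAR_i)} across all trials of the
#' stimuli in the bin.  The result is the n_bins-dimensional pattern of
#' unbiased performances used for consistency comparisons.
#'
#' @param choice_table data.frame with columns stimulus_id, choice
#'   ("word"/"pseudoword"), lexical_class and mean_bigram_freq (one row per
#'   trial; multiple subjects are pooled).
#' @param n_bins number of frequency bins (default 10).
#' @return A list of class \code{behavioral_signature}: \code{dprime_per_bin},
#'   \code{HR}, \code{FAR}, \code{n_trials_per_bin}, \code{bin_of_stimulus}.
#' @export
binned_signature <- function(choice_table, n_bins = 10) {
  need <- c("stimulus_id", "choice", "lexical_class", "mean_bigram_freq")
  stopifnot(all(need %in% names(choice_table)))
  stim <- unique(choice_table[, c("stimulus_id", "lexical_class",
                                  "mean_bigram_freq")])
  bin <- .assign_freq_bins(stim, n_bins)
  names(bin) <- stim$stimulus_id
  ct_bin <- bin[choice_table$stimulus_id]
  is_word_stim <- choice_table$lexical_class == "word"
  said_word <- choice_table$choice == "word"
  dp <- HR <- FAR <- nt <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    iw <- ct_bin == b & is_word_stim
    ip <- ct_bin == b & !is_word_stim
    if (!any(iw) || !any(ip)) stop("bin ", b, " lacks trials of one class")
    HR[b] <- mean(said_word[iw]); FAR[b] <- mean(said_word[ip])
    nt[b] <- sum(iw) + sum(ip)
    dp[b] <- dprime(HR[b], FAR[b], n_hit = sum(iw), n_fa = sum(ip))
  }
  structure(list(dprime_per_bin = dp, HR = HR, FAR = FAR,
                 n_trials_per_bin = nt, n_bins = n_bins,
                 bin_of_stimulus = bin),
            class = "behavioral_signature")
}

.split_trials <- function(ct) {
  # random half-split of trials within each (subject, stimulus)
  key <- paste(ct$subject_id, ct$stimulus_id)
  ord <- stats::ave(seq_along(key), key, FUN = function(i) sample(seq_along(i)))
  cnt <- stats::ave(seq_along(key), key, FUN = length)
  first <- ord <= cnt / 2
  list(ct[first, , drop = FALSE], ct[!first, , drop = FALSE])
}

#' Noise-adjusted behavioral consistency
#'
#' Consistency between two systems' binned behavioral signatures,
#' \deqn{\tilde\rho(m,p) = \rho(m,p) / \sqrt{\rho(m,m)\,\rho(p,p)}}
#' where \eqn{\rho(m,p)} is the Pearson correlation between independent
#' split-half estimates of the two signatures and \eqn{\rho(m,m)},
#' \eqn{\rho(p,p)} are each system's split-half internal reliabilities.
#' Trials are randomly split in half within each (subject, stimulus); the
#' raw cross-system correlation is averaged over the four cross-half
#' pairings.  All correlations use the same number of trials, so no
#' extrapolation formula is needed.  The procedure is repeated
#' \code{n_resplits} times and the mean is reported.  A non-positive
#' reliability leaves that resplit's estimate undefined (NA) rather than
#' coercing it.
#'
#' @param m_table,p_table choice tables (see [binned_signature()]; a
#'   subject_id column is required for trial splitting).
#' @param n_resplits number of random resplits (default 10).
#' @param n_bins signature length (default 10).
#' @param seed seed for the resplits.
#' @return A list of class \code{consistency_estimate}: \code{rho_tilde}
#'   (mean over resplits), \code{per_resplit} (data.frame with rho_tilde,
#'   raw_rho, reliability_m, reliability_p), \code{n_resplits}.
#' @export
consistency <- function(m_table, p_table, n_resplits = 10, n_bins = 10,
                        seed = 1) {
  for (tb in list(m_table, p_table))
    if (min(table(paste(tb$subject_id, tb$stimulus_id))) < 2)
      stop("need >= 2 trials per (subject, stimulus) for split-half consistency")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- lapply(seq_len(n_resplits), function(it) {
    ms <- .split_trials(m_table)
    ps <- .split_trials(p_table)
    sig <- function(tb) binned_signature(tb, n_bins)$dprime_per_bin
    m1 <- sig(ms[[1]]); m2 <- sig(ms[[2]])
    p1 <- sig(ps[[1]]); p2 <- sig(ps[[2]])
    raw <- mean(c(stats::cor(m1, p1), stats::cor(m1, p2),
                  stats::cor(m2, p1), stats::cor(m2, p2)))
    rm <- stats::cor(m1, m2); rp <- stats::cor(p1, p2)
    rt <- if (is.finite(rm) && is.finite(rp) && rm > 0 && rp > 0)
      raw / sqrt(rm * rp) else NA_real_
    data.frame(rho_tilde = rt, raw_rho = raw,
               reliability_m = rm, reliability_p = rp)
  })
  per <- do.call(rbind, res)
  structure(list(rho_tilde = mean(per$rho_tilde, na.rm = TRUE),
                 per_resplit = per, n_resplits = n_resplits,
                 n_undefined = sum(is.na(per$rho_tilde))),
            class = "consistency_estimate")
}

#' @export
print.consistency_estimate <- function(x, ...) {
  cat(sprintf("noise-adjusted consistency rho~ = %.3f (mean of %d resplits%s)\n",
              x$rho_tilde, x$n_resplits,
              if (x$n_undefined > 0)
                paste0(", ", x$n_undefined, " undefined") else ""))
  invisible(x)
}

#' Leave-one-subject-out consistency ceiling
#'
#' For each subject, estimates the consistency between that subject's choice
#' table and the pooled table of the remaining subjects.  The distribution
#' of these hold-out estimates is the behavioral ceiling against which a
#' decoder's consistency is judged.
#'
#' @param choice_table pooled choice table with >= 2 distinct subjects.
#' @param ... passed to [consistency()].
#' @return A data.frame with one row per subject (subject_id, rho_tilde)
#'   plus attributes \code{median} and \code{IQR}.
#' @export
pool_and_holdout_consistency <- function(choice_table, ...) {
  subjects <- unique(choice_table$subject_id)
  if (length(subjects) < 2) stop("need >= 2 subjects")
  est <- vapply(subjects, function(s) {
    m <- choice_table[choice_table$subject_id == s, , drop = FALSE]
    p <- choice_table[choice_table$subject_id != s, , drop = FALSE]
    consistency(m, p, ...)$rho_tilde
  }, 0)
  out <- data.frame(subject_id = subjects, rho_tilde = est,
                    stringsAsFactors = FALSE)
  attr(out, "median") <- stats::median(est)
  attr(out, "IQR") <- stats::IQR(est)
  out
}
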