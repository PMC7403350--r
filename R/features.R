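#' Repetition-averaged population features
#'
#' Averages a response tensor over repetitions and returns a feature-by-
#' stimulus matrix for decoding.  With \code{window_selection =
#' "both_concatenated"} (the decoding default) the two response windows are
#' concatenated site-wise so each site contributes two features; single-site
#' analyses use \code{"early_only"} (70-170 ms).
#'
#' @param tensor a \code{response_tensor}.
#' @param window_selection \code{"both_concatenated"}, \code{"early_only"}
#'   or \code{"late_only"}.
#' @return A \code{population_features} list: \code{matrix} (features x
#'   stimuli), \code{site_ids} (parallel to rows), \code{stimulus_ids}.
#' @export
average_repetitions <- function(tensor,
                                window_selection = c("both_concatenated",
                                                     "early_only",
                                                     "late_only")) {
  window_selection <- match.arg(window_selection)
  d <- dim(tensor$rates)
  if (any(d[1:3] == 0)) stop("empty tensor")
  m1 <- apply(tensor$rates[, , , 1, drop = FALSE], c(1, 2), mean)
  if (window_selection == "early_only") {
    mat <- m1; ids <- tensor$site_meta$site_id
  } else {
    m2 <- apply(tensor$rates[, , , 2, drop = FALSE], c(1, 2), mean)
    if (window_selection == "late_only") {
      mat <- m2; ids <- tensor$site_meta$site_id
    } else {
      mat <- rbind(m1, m2)
      ids <- rep(tensor$site_meta$site_id, 2)
    }
  }
  structure(list(matrix = mat, site_ids = ids,
                 stimulus_ids = tensor$stimulus_ids,
                 window_selection = window_selection),
            class = "population_features")
}

#' Screen sites for significant visual drive
#'
#' Two-sided Wilcoxon signed-rank test per site of trial-wise evoked rates
#' (early window) against the paired baseline rates, pooled over stimuli and
#' repetitions.  Sites pass at \code{p < alpha} (default 0.001).
#'
#' @param tensor a \code{response_tensor} carrying per-trial baseline rates.
#' @param alpha significance level (default 0.001).
#' @return A data.frame: site_id, statistic, p, visually_driven.
#' @export
screen_visual_drive <- function(tensor, alpha = 0.001) {
  if (is.null(tensor$baseline)) stop("tensor has no baseline rates")
  ns <- dim(tensor$rates)[1]
  out <- lapply(seq_len(ns), function(s) {
    ev <- as.numeric(tensor$rates[s, , , 1])
    bl <- as.numeric(tensor$baseline[s, , ])
    dif <- ev - bl
    if (all(dif == 0)) return(data.frame(site_id = tensor$site_meta$site_id[s],
                                         statistic = NA_real_, p = 1,
                                         visually_driven = FALSE))
    wt <- suppressWarnings(stats::wilcox.test(dif, alternative = "two.sided",
                                              exact = FALSE, correct = TRUE))
    data.frame(site_id = tensor$site_meta$site_id[s],
               statistic = unname(wt$statistic), p = wt$p.value,
               visually_driven = wt$p.value < alpha)
  })
  do.call(rbind, out)
}

#' Screen sites for reliable letter tuning
#'
#' Split-half reliability of each site's response pattern over the single-
#' letter stimulus set: repetitions are split at random into two halves, the
#' two half-mean response patterns are Pearson-correlated across letter
#' stimuli, and the correlation is averaged over \code{n_splits} random
#' resplits.  The reported reliability is the resplit average; the p-value
#' uses the first split only (one-sided t-transform of Pearson's r), so that
#' it stays a calibrated p-value — averaging correlations before the
#' t-transform would shrink the null distribution and overstate
#' significance.
#'
#' @param tensor a \code{response_tensor}.
#' @param letter_idx indices (or logical mask) of the letter stimuli within
#'   the tensor's stimulus axis; defaults to all stimuli whose metadata
#'   class is \code{"letter"}.
#' @param alpha significance level (default 0.01).
#' @param n_splits number of random resplits to average (default 20).
#' @param seed seed for the resplits.
#' @return A data.frame: site_id, split_half_r, p, reliable_letters.
#' @export
screen_letter_reliability <- function(tensor, letter_idx = NULL, alpha = 0.01,
                                      n_splits = 20, seed = 1) {
  d <- dim(tensor$rates)
  if (d[3] < 2) stop("split-half reliability requires >= 2 repetitions")
  if (is.null(letter_idx)) {
    if (is.null(tensor$stim_meta)) stop("no stimulus metadata; supply letter_idx")
    letter_idx <- which(tensor$stim_meta$lexical_class == "letter")
  }
  if (is.logical(letter_idx)) letter_idx <- which(letter_idx)
  if (length(letter_idx) < 3) stop("too few letter stimuli for reliability")
  x <- tensor$rates[, letter_idx, , 1, drop = FALSE]
  dim(x) <- dim(x)[1:3]
  nr <- d[3]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- floor(nr / 2)
  rs <- matrix(NA_real_, d[1], n_splits)
  for (it in seq_len(n_splits)) {
    i1 <- sample.int(nr, half)
    m1 <- apply(x[, , i1, drop = FALSE], c(1, 2), mean)
    m2 <- apply(x[, , -i1, drop = FALSE], c(1, 2), mean)
    rs[, it] <- vapply(seq_len(d[1]), function(s) {
      if (stats::sd(m1[s, ]) == 0 || stats::sd(m2[s, ]) == 0) return(0)
      stats::cor(m1[s, ], m2[s, ])
    }, 0)
  }
  r_bar <- rowMeans(rs)
  n <- length(letter_idx)
  r1 <- rs[, 1]
  tstat <- r1 * sqrt((n - 2) / pmax(1 - r1^2, 1e-12))
  p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)  # one-sided: positive r
  data.frame(site_id = tensor$site_meta$site_id,
             split_half_r = r_bar, p = p,
             reliable_letters = p < alpha)
}
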