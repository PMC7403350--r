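#' 26-way letter-decoder embedding
#'
#' Trains a multinomial logistic (ridge) decoder to identify the 26 letters
#' from the population features, cross-validated over positions: the
#' embedding of a letter at position p comes from a decoder trained on the
#' other three positions only, preventing memorization of the embedded
#' stimuli.  The embedding of a (letter, position) is the decoder's
#' 26-dimensional class-probability vector, averaged over the case/size
#' variations at that position.
#'
#' @param features a \code{population_features} covering the letter stimuli.
#' @param letter_meta metadata rows of the letter stimuli (text,
#'   position_slot, stimulus_id).
#' @param lambda ridge penalty (frozen package default).
#' @param seed integer seed (glmnet is deterministic; kept for interface
#'   symmetry).
#' @return A 26 x 4 x 26 array \code{emb[letter, position, class]} with
#'   rows summing to 1 across classes.
#' @export
letter_decoder_embedding <- function(features, letter_meta,
                                     lambda = .ORTHO_MULTINOM_LAMBDA, seed = 1) {
  f <- .as_features(features)
  lm <- letter_meta[letter_meta$lexical_class == "letter", , drop = FALSE]
  if (!all(LETTERS %in% lm$text) || !all(1:4 %in% lm$position_slot))
    stop("need all 26 letters at all 4 positions")
  col <- match(lm$stimulus_id, f$stimulus_ids)
  if (anyNA(col)) stop("features missing letter stimuli")
  x_all <- t(f$matrix[, col, drop = FALSE])
  y_all <- factor(lm$text, levels = LETTERS)
  pos <- lm$position_slot
  emb <- array(NA_real_, c(26, 4, 26),
               dimnames = list(LETTERS, paste0("p", 1:4), LETTERS))
  for (p in 1:4) {
    tr <- pos != p; te <- pos == p
    mu <- colMeans(x_all[tr, , drop = FALSE])
    sg <- apply(x_all[tr, , drop = FALSE], 2, stats::sd); sg[sg == 0] <- 1
    xtr <- sweep(sweep(x_all[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(x_all[te, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- glmnet::glmnet(xtr, y_all[tr], family = "multinomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    pr <- stats::predict(fit, xte, type = "response")[, , 1]
    te_letters <- as.character(y_all[te])
    for (L in LETTERS)
      emb[L, p, ] <- colMeans(pr[te_letters == L, , drop = FALSE])
  }
  emb
}

#' Decoder-space similarity of letter pairs
#'
#' Pearson correlation between the 26-dimensional decoder embeddings of two
#' letters at one position, averaged over the four positions; computed for
#' every unordered pair of distinct letters (325 pairs for the full
#' alphabet).
#'
#' @param embedding array from [letter_decoder_embedding()].
#' @return data.frame: letter_a, letter_b, r_IT.
#' @export
pair_similarity <- function(embedding) {
  ltrs <- dimnames(embedding)[[1]]
  n <- length(ltrs)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    rs <- vapply(seq_len(dim(embedding)[2]), function(p)
      stats::cor(embedding[i, p, ], embedding[j, p, ]), 0)
    out[[k]] <- data.frame(letter_a = ltrs[i], letter_b = ltrs[j],
                           r_IT = mean(rs), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Relate decoder similarity to pairwise reflectivity
#'
#' Joins r_IT with the pixel-reflectivity difference
#' \eqn{\Delta R = R_H - R_V} per letter pair, computes a boxcar rolling
#' average of r_IT along sorted \eqn{\Delta R}, bins \eqn{\Delta R} into
#' \code{n_bins} equal-range bins, and tests (i) each extreme bin's mean
#' r_IT against zero (one-tailed one-sample t) and (ii) rightmost vs
#' leftmost bin (one-tailed unpaired two-sample t, H1: rightmost greater).
#' Identity pairs never enter: the pair table contains distinct letters
#' only.
#'
#' @param pair_table merge of [pair_similarity()] and
#'   [all_letter_pair_reflectivity()] (needs columns r_IT and delta_R).
#' @param n_bins number of equal-range bins (default 3).
#' @param boxcar rolling-average window in pairs (default 5).
#' @return List: \code{pairs} (sorted, with rolling average),
#'   \code{bin_summary} (mean, SE, n per bin), \code{p_rightmost},
#'   \code{p_leftmost}, \code{p_right_vs_left}.
#' @export
deltaR_analysis <- function(pair_table, n_bins = 3, boxcar = 5) {
  stopifnot(all(c("r_IT", "delta_R") %in% names(pair_table)))
  if (nrow(pair_table) < n_bins * 2) stop("too few pairs for binning")
  tb <- pair_table[order(pair_table$delta_R), , drop = FALSE]
  tb$rolling_r <- as.numeric(stats::filter(tb$r_IT, rep(1 / boxcar, boxcar),
                                           sides = 2))
  tb$bin <- if (n_bins == 1) rep(1L, nrow(tb)) else
    cut(tb$delta_R, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  bs <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    v <- tb$r_IT[tb$bin == b]
    v <- v[is.finite(v)]
    data.frame(bin = b, n = length(v),
               mean_r = if (length(v)) mean(v) else NA_real_,
               se_r = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                      else NA_real_)
  }))
  left <- tb$r_IT[tb$bin == 1]; left <- left[is.finite(left)]
  right <- tb$r_IT[tb$bin == n_bins]; right <- right[is.finite(right)]
  t1 <- function(v) if (length(v) > 1 && stats::sd(v) > 0)
    stats::t.test(v, alternative = "greater")$p.value else NA_real_
  p_rl <- if (length(left) > 1 && length(right) > 1)
    stats::t.test(right, left, alternative = "greater",
                  var.equal = FALSE)$p.value else NA_real_
  list(pairs = tb, bin_summary = bs,
       p_rightmost = t1(right), p_leftmost = t1(left),
       p_right_vs_left = p_rl)
}

#' Full mirror-symmetry analysis from a response tensor
#'
#' Convenience wrapper: embeds letters through the cross-validated 26-way
#' decoder, computes pairwise r_IT, joins the glyph reflectivity table for
#' the same font, and summarizes the \eqn{\Delta R} dependence.
#'
#' @param tensor a \code{response_tensor} containing the full letter set.
#' @param config the [stim_config()] whose font defines reflectivity.
#' @param font_case,font_size variation used for the reflectivity glyphs.
#' @param ... passed to [deltaR_analysis()].
#' @return The [deltaR_analysis()] summary, with the joined pair table.
#' @export
mirror_symmetry_analysis <- function(tensor, config = stim_config(),
                                     font_case = "lower",
                                     font_size = "medium", ...) {
  feats <- average_repetitions(tensor, "both_concatenated")
  lm <- tensor$stim_meta[tensor$stim_meta$lexical_class == "letter", ]
  emb <- letter_decoder_embedding(feats, lm)
  sim <- pair_similarity(emb)
  refl <- all_letter_pair_reflectivity(
    render_letter_images(LETTERS, font_case = font_case,
                         font_size = font_size, config = config))
  tb <- merge(sim, refl, by = c("letter_a", "letter_b"))
  deltaR_analysis(tb, ...)
}
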