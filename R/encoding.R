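.canonical_string_idx <- function(sm, font_case, font_size) {
  which(sm$lexical_class %in% c("word", "pseudoword") &
          sm$font_case == font_case & sm$font_size == font_size)
}

#' Letter-at-position predictor matrix for one site
#'
#' For each canonical-view letter string, builds the vector of the site's
#' own repetition-averaged responses to the string's constituent letters at
#' their positions (e.g. for "ABCD": responses to A at slot 1, B at slot 2,
#' C at slot 3, D at slot 4).  The \code{"bag_of_letters"} model instead
#' looks letters up at the wrong position, through one fixed random
#' derangement of the four slots shared by all strings.
#'
#' @param tensor a \code{response_tensor} containing both string and letter
#'   stimuli at the canonical case/size.
#' @param site site index.
#' @param model \code{"full_4"} (position-specific) or
#'   \code{"bag_of_letters"}.
#' @param font_case,font_size canonical variation to match between strings
#'   and letters (defaults upper/medium).
#' @param bag_seed seed fixing the bag-model slot permutation.
#' @return List: \code{X} (strings x 4 predictor matrix), \code{y}
#'   (measured string responses), \code{string_idx} (tensor columns),
#'   \code{perm} (slot permutation used).
#' @export
letter_predictor_matrix <- function(tensor, site,
                                    model = c("full_4", "bag_of_letters"),
                                    font_case = "upper", font_size = "medium",
                                    bag_seed = 1) {
  model <- match.arg(model)
  sm <- tensor$stim_meta
  if (is.null(sm)) stop("tensor lacks stimulus metadata")
  si <- .canonical_string_idx(sm, font_case, font_size)
  if (length(si) == 0) stop("no canonical-view string stimuli in tensor")
  li <- which(sm$lexical_class == "letter" & sm$font_case == font_case &
                sm$font_size == font_size)
  if (length(li) == 0) stop("no canonical-view letter stimuli in tensor")
  lkey <- paste(sm$text[li], sm$position_slot[li])
  lresp <- rowMeans(matrix(tensor$rates[site, li, , 1], nrow = length(li)))
  names(lresp) <- lkey

  perm <- 1:4
  if (model == "bag_of_letters") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(bag_seed)
    repeat {
      perm <- sample(4)
      if (all(perm != 1:4)) break
    }
  }
  X <- matrix(NA_real_, length(si), 4,
              dimnames = list(sm$stimulus_id[si], paste0("slot", 1:4)))
  for (j in seq_along(si)) {
    ltr <- strsplit(sm$text[si[j]], "")[[1]]
    key <- paste(ltr, perm)
    if (anyNA(match(key, lkey)))
      stop("missing letter-at-slot response: ",
           paste(setdiff(key, lkey), collapse = ", "))
    X[j, ] <- lresp[key]
  }
  y <- rowMeans(matrix(tensor$rates[site, si, , 1], nrow = length(si)))
  list(X = X, y = y, string_idx = si, perm = perm)
}

.split_half_reliability_sb <- function(x, n_splits = 10, seed = 1) {
  # x: stimuli x reps; Spearman-Brown-corrected split-half reliability of
  # the full repetition average
  nr <- ncol(x)
  if (nr < 2) stop("need >= 2 repetitions for reliability")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- floor(nr / 2)
  rs <- vapply(seq_len(n_splits), function(i) {
    i1 <- sample.int(nr, half)
    m1 <- rowMeans(x[, i1, drop = FALSE])
    m2 <- rowMeans(x[, -i1, drop = FALSE])
    if (stats::sd(m1) == 0 || stats::sd(m2) == 0) return(NA_real_)
    stats::cor(m1, m2)
  }, 0)
  r <- mean(rs, na.rm = TRUE)
  2 * r / (1 + r)
}

#' Cross-validated reconstruction of string responses from letter responses
#'
#' Tests whether a site's letter-string responses are a linear combination
#' of its single-letter responses.  For each site, string responses are
#' regressed (with intercept) on the letter-at-position predictors,
#' cross-validating over strings; the held-out predictions are correlated
#' with the measured responses and the correlation is noise-adjusted by the
#' (Spearman-Brown corrected) split-half reliability of the measured string
#' responses, so a fully predictive model scores around 1 regardless of the
#' finite repetition count.  Substring models (\code{best_3}, \code{best_2},
#' \code{best_1}) exhaustively search the slot subsets on the training folds
#' only (ties broken towards the lowest slot indices), keeping selection and
#' testing independent.
#'
#' @param tensor a \code{response_tensor} with canonical string and letter
#'   stimuli.
#' @param model one of \code{"full_4"}, \code{"best_3"}, \code{"best_2"},
#'   \code{"best_1"}, \code{"bag_of_letters"}.
#' @param sites site indices (default: all).
#' @param n_folds CV folds over strings (default 10).
#' @param seed integer seed (folds and reliability splits).
#' @param ... passed to [letter_predictor_matrix()].
#' @return data.frame: site, model, rho_tilde, rho_raw, reliability,
#'   selected_slots (most frequently selected training subset, for
#'   substring models).
#' @export
fit_reconstruction <- function(tensor,
                               model = c("full_4", "best_3", "best_2",
                                         "best_1", "bag_of_letters"),
                               sites = NULL, n_folds = 10, seed = 1, ...) {
  model <- match.arg(model)
  k_sub <- switch(model, best_3 = 3, best_2 = 2, best_1 = 1, 4L)
  base_model <- if (model == "bag_of_letters") "bag_of_letters" else "full_4"
  d <- dim(tensor$rates)
  if (is.null(sites)) sites <- seq_len(d[1])
  out <- vector("list", length(sites))
  for (ii in seq_along(sites)) {
    s <- sites[ii]
    pm <- letter_predictor_matrix(tensor, s, model = base_model, ...)
    X <- pm$X; y <- pm$y
    n <- length(y)
    if (n < n_folds) stop("fewer strings (", n, ") than folds (", n_folds, ")")
    old <- .Random.seed_save()
    set.seed(seed)
    fold <- sample(rep(seq_len(n_folds), length.out = n))
    pred <- numeric(n)
    sel_count <- integer(0)
    subsets <- utils::combn(4, k_sub, simplify = FALSE)
    for (k in seq_len(n_folds)) {
      te <- fold == k
      Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
      if (length(subsets) == 1) {
        best <- subsets[[1]]
      } else {
        rss <- vapply(subsets, function(ss) {
          f <- stats::lm.fit(cbind(1, Xtr[, ss, drop = FALSE]), ytr)
          sum(f$residuals^2)
        }, 0)
        best <- subsets[[which.min(rss)]]  # which.min ties -> lowest slots
      }
      key <- paste(best, collapse = "")
      sel_count[key] <- if (is.na(sel_count[key])) 1L else sel_count[key] + 1L
      f <- stats::lm.fit(cbind(1, Xtr[, best, drop = FALSE]), ytr)
      pred[te] <- cbind(1, X[te, best, drop = FALSE]) %*% f$coefficients
    }
    rho_raw <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, y)
    rel <- .split_half_reliability_sb(
      matrix(tensor$rates[s, pm$string_idx, , 1],
             nrow = length(pm$string_idx)), seed = seed)
    rho_tilde <- if (is.finite(rel) && rel > 0) rho_raw / sqrt(rel) else NA_real_
    .Random.seed_restore(old)
    out[[ii]] <- data.frame(
      site = s, model = model, rho_tilde = rho_tilde, rho_raw = rho_raw,
      reliability = rel,
      selected_slots = names(sel_count)[which.max(sel_count)],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' One-tailed bootstrap test on distribution medians
#'
#' Tests whether the median of \code{fits_a$rho_tilde} exceeds that of
#' \code{fits_b$rho_tilde} across the common sites, by bootstrap resampling
#' sites (paired) and comparing the resampled medians.
#'
#' @param fits_a,fits_b data.frames from [fit_reconstruction()] over the
#'   same sites.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return List: median_a, median_b, p (one-tailed, H1: median_a >
#'   median_b).
#' @export
compare_model_medians <- function(fits_a, fits_b, n_boot = 1000, seed = 1) {
  common <- intersect(fits_a$site, fits_b$site)
  if (length(common) == 0) stop("no common sites between the two fits")
  a <- fits_a$rho_tilde[match(common, fits_a$site)]
  b <- fits_b$rho_tilde[match(common, fits_b$site)]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(a)
  d_boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    stats::median(a[idx]) - stats::median(b[idx])
  }, 0)
  list(median_a = stats::median(a), median_b = stats::median(b),
       p = (1 + sum(d_boot <= 0)) / (n_boot + 1))
}
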