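#' Single-site selectivity d'
#'
#' Standardized mean difference between a site's responses to two stimulus
#' classes, \eqn{d' = (\mu_x - \mu_y)/\sqrt{(\sigma_x^2 + \sigma_y^2)/2}},
#' with means and SDs taken across stimuli of repetition-averaged responses.
#' Positive values indicate preference for class x.
#'
#' @param rates_x,rates_y repetition-averaged responses to the stimuli of
#'   each class (>= 2 stimuli per class).
#' @return d' (unitless).
#' @export
selectivity_dprime <- function(rates_x, rates_y) {
  stopifnot(length(rates_x) >= 2, length(rates_y) >= 2)
  pooled <- (stats::var(rates_x) + stats::var(rates_y)) / 2
  if (pooled == 0) stop("zero pooled variance: d' undefined")
  (mean(rates_x) - mean(rates_y)) / sqrt(pooled)
}

#' Bootstrap exact test of single-site selectivity
#'
#' Resamples stimuli with replacement within each class, recomputes d' for
#' each bootstrap sample, and infers two-tailed significance from the
#' distance of the observed d' from zero in units of the bootstrap
#' distribution's spread: \eqn{p = 2\,\Phi(-|d'|/\mathrm{sd}(d'_b))}.  (The
#' alternative rule that counts bootstrap mass across zero is
#' anticonservative for this statistic — its false-positive rate exceeds the
#' nominal level under exchangeable nulls — so the spread-based form is
#' used.)
#'
#' @param rates repetition-averaged responses, one per stimulus.
#' @param labels logical vector, TRUE for class-x stimuli.
#' @param n_boot bootstrap samples (default 100; must be > 1).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return A list of class \code{selectivity_result}: \code{dprime},
#'   \code{boot} (bootstrap d' values), \code{p_two_tailed},
#'   \code{significant}.
#' @export
bootstrap_selectivity_test <- function(rates, labels, n_boot = 100,
                                       alpha = 0.05, seed = 1) {
  labels <- as.logical(labels)
  stopifnot(length(rates) == length(labels))
  if (n_boot < 2) stop("n_boot must be at least 2 to form a two-tailed p")
  x <- rates[labels]; y <- rates[!labels]
  if (length(x) < 2 || length(y) < 2) stop("both classes need >= 2 stimuli")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bx <- matrix(x[sample.int(length(x), length(x) * n_boot, replace = TRUE)],
               ncol = n_boot)
  by <- matrix(y[sample.int(length(y), length(y) * n_boot, replace = TRUE)],
               ncol = n_boot)
  vx <- apply(bx, 2, stats::var); vy <- apply(by, 2, stats::var)
  pooled <- (vx + vy) / 2
  ok <- pooled > 0
  boot <- (colMeans(bx) - colMeans(by))[ok] / sqrt(pooled[ok])
  if (length(boot) < 2) stop("bootstrap degenerate: all resamples had zero variance")
  dhat <- selectivity_dprime(x, y)
  se <- stats::sd(boot)
  p <- if (se == 0) as.numeric(dhat == 0) else
    min(1, 2 * stats::pnorm(-abs(dhat) / se))
  structure(list(dprime = dhat, boot = boot,
                 p_two_tailed = p, significant = p < alpha,
                 n_boot = n_boot, n_degenerate = sum(!ok)),
            class = "selectivity_result")
}

#' Selectivity tests for every site of a feature matrix
#'
#' Applies [bootstrap_selectivity_test()] site-wise to a sites x stimuli
#' matrix of repetition-averaged responses.
#'
#' @param resp sites x stimuli matrix.
#' @param labels logical class labels (length = ncol).
#' @param ... passed to [bootstrap_selectivity_test()].
#' @param seed base seed; site s uses seed + s.
#' @return data.frame: site (row index), dprime, p, significant.
#' @export
site_selectivity_table <- function(resp, labels, seed = 1, ...) {
  out <- lapply(seq_len(nrow(resp)), function(s) {
    r <- bootstrap_selectivity_test(resp[s, ], labels, seed = seed + s, ...)
    data.frame(site = s, dprime = r$dprime, p = r$p_two_tailed,
               significant = r$significant)
  })
  do.call(rbind, out)
}

#' Binomial test for the fraction of selective sites
#'
#' Exact upper-tail probability of observing at least \code{n_selective}
#' significant sites out of \code{n_total} when each is significant with
#' probability \code{p0} (the nominal test level).
#'
#' @param n_selective,n_total counts.
#' @param p0 success probability under the null (default 0.05).
#' @return Tail p-value.
#' @export
selective_fraction_test <- function(n_selective, n_total, p0 = 0.05) {
  stopifnot(n_selective >= 0, n_selective <= n_total, n_total >= 1)
  stats::pbinom(n_selective - 1, n_total, p0, lower.tail = FALSE)
}

#' Hemispheric bias test for selective sites
#'
#' Two-sided exact binomial test of the hemisphere composition of the
#' selective subpopulation against the hemisphere sampling fraction of the
#' full population.
#'
#' @param hemispheres character vector of hemisphere labels for the
#'   selective sites.
#' @param sampling_fraction expected fraction in \code{reference} hemisphere.
#' @param reference which hemisphere the fraction refers to.
#' @return Two-sided p-value.
#' @export
hemisphere_bias_test <- function(hemispheres, sampling_fraction = 0.5,
                                 reference = "left") {
  if (length(hemispheres) == 0 || anyNA(hemispheres))
    stop("hemisphere labels missing")
  x <- sum(hemispheres == reference)
  stats::binom.test(x, length(hemispheres), p = sampling_fraction,
                    alternative = "two.sided")$p.value
}

#' Sparsity index of a response vector
#'
#' \eqn{A(x) = E[x]^2 / E[x^2]}, \eqn{SI(x) = (1 - A(x))/(1 - 1/N)} with N
#' the vector length.  In the noise-free limit SI is 0 for a perfectly
#' uniform response pattern and 1 for a perfectly one-hot pattern.
#' Negative entries (possible after averaging under a gaussian noise model)
#' are rectified at zero before the computation.
#'
#' @param x response vector, length >= 2, not all zero after rectification.
#' @return SI in [0, 1].
#' @export
sparsity_index <- function(x) {
  stopifnot(length(x) >= 2)
  x <- pmax(x, 0)
  if (all(x == 0)) stop("all-zero response vector: SI undefined")
  A <- mean(x)^2 / mean(x^2)
  (1 - A) / (1 - 1 / length(x))
}

#' Null sparsity distributions preserving repetition noise
#'
#' Simulates the sparsity index expected under two extreme tuning
#' hypotheses while keeping the site's trial-to-trial variability:
#' \describe{
#'   \item{uniform}{the stimulus category is shuffled independently on each
#'     repetition before repetition-averaging, destroying tuning but keeping
#'     noise — the SI a uniformly responding site of this noise level would
#'     show.}
#'   \item{one-hot}{half the repetitions identify the top category; on the
#'     held-out half the top category keeps its responses while all other
#'     categories are rebuilt from the minimum category mean plus resampled
#'     trial residuals — the SI a perfectly one-hot site of this noise level
#'     would show.}
#' }
#'
#' @param resp category x repetition response matrix for one site (e.g. the
#'   26 letters, each column one repetition; see
#'   [site_category_responses()]).
#' @param n_perm null iterations (default 100).
#' @param seed integer seed.
#' @return A list of class \code{sparsity_result}: \code{SI} (empirical, on
#'   the repetition-averaged vector), \code{null_uniform},
#'   \code{null_onehot} (length-n_perm distributions), \code{N}.
#' @export
sparsity_nulls <- function(resp, n_perm = 100, seed = 1) {
  stopifnot(is.matrix(resp), nrow(resp) >= 2, ncol(resp) >= 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_cat <- nrow(resp); n_rep <- ncol(resp)
  si_emp <- sparsity_index(rowMeans(resp))
  null_u <- null_o <- numeric(n_perm)
  half <- floor(n_rep / 2)
  for (it in seq_len(n_perm)) {
    shuf <- apply(resp, 2, sample)           # shuffle categories per repetition
    null_u[it] <- sparsity_index(rowMeans(shuf))
    i1 <- sample.int(n_rep, half)
    top <- which.max(rowMeans(resp[, i1, drop = FALSE]))
    h2 <- resp[, -i1, drop = FALSE]
    resid <- h2 - rowMeans(h2)
    v <- numeric(n_cat)
    v[top] <- mean(h2[top, ])
    lo <- min(rowMeans(h2))
    others <- setdiff(seq_len(n_cat), top)
    rs <- matrix(sample(resid, length(others) * ncol(h2), replace = TRUE),
                 nrow = length(others))
    v[others] <- lo + rowMeans(rs)
    null_o[it] <- sparsity_index(v)
  }
  structure(list(SI = si_emp, null_uniform = null_u, null_onehot = null_o,
                 N = n_cat, n_perm = n_perm),
            class = "sparsity_result")
}

#' Per-category trial responses of one site
#'
#' Builds the category x repetition matrix used by [sparsity_nulls()]:
#' for \code{axis = "letters"}, the response at repetition r to a letter is
#' the mean over that letter's stimuli (positions and variations) at
#' repetition r; for \code{axis = "positions"}, over that slot's stimuli.
#'
#' @param tensor a \code{response_tensor} containing letter stimuli.
#' @param site site index.
#' @param axis \code{"letters"} or \code{"positions"}.
#' @return A category x repetition matrix (26 x reps or 4 x reps).
#' @export
site_category_responses <- function(tensor, site,
                                    axis = c("letters", "positions")) {
  axis <- match.arg(axis)
  sm <- tensor$stim_meta
  idx <- which(sm$lexical_class == "letter")
  if (length(idx) == 0) stop("tensor contains no letter stimuli")
  cat_of <- if (axis == "letters") sm$text[idx] else
    as.character(sm$position_slot[idx])
  cats <- sort(unique(cat_of))
  x <- tensor$rates[site, idx, , 1]
  t(sapply(cats, function(cc) colMeans(x[cat_of == cc, , drop = FALSE])))
}

#' Permutation test of median SI against a null hypothesis
#'
#' Compares the across-site median of empirical sparsity indices to the
#' distribution of across-site medians under a simulated null (one median
#' per null iteration).
#'
#' @param si_empirical per-site empirical SI values.
#' @param si_null sites x iterations matrix of null SI values.
#' @param alternative \code{"greater"} (empirical median above the null) or
#'   \code{"less"}.
#' @return List: median_empirical, median_null (vector), p.
#' @export
sparsity_median_test <- function(si_empirical, si_null,
                                 alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  med_e <- stats::median(si_empirical)
  med_n <- apply(si_null, 2, stats::median)
  p <- if (alternative == "greater")
    (1 + sum(med_n >= med_e)) / (length(med_n) + 1)
  else
    (1 + sum(med_n <= med_e)) / (length(med_n) + 1)
  list(median_empirical = med_e, median_null = med_n, p = p)
}

.moran_weights <- function(rows, cols, adjacency) {
  n <- length(rows)
  dr <- abs(outer(rows, rows, "-"))
  dc <- abs(outer(cols, cols, "-"))
  w <- if (adjacency == "rook") (dr + dc) == 1 else
    (pmax(dr, dc) == 1)
  w <- w * 1
  diag(w) <- 0
  rs <- rowSums(w)
  if (any(rs == 0)) rs[rs == 0] <- 1   # isolated electrodes contribute zero
  w / rs
}

.moran_stat <- function(z, W) {
  # row-standardized weights: S0 = n, so I = z' W z / z' z
  as.numeric(z %*% W %*% z) / sum(z^2)
}

#' Moran's I spatial autocorrelation on an electrode grid
#'
#' Computes Moran's I for site values placed on a 10 x 10 electrode grid
#' with rook (default) or queen adjacency and row-standardized weights, and
#' a permutation p-value obtained by shuffling values across occupied
#' electrodes.
#'
#' @param values numeric values (e.g. selectivity d') per site.
#' @param grid_row,grid_col integer grid coordinates (0-9).
#' @param adjacency \code{"rook"} or \code{"queen"}.
#' @param n_perm permutations (default 100, the minimum honoured).
#' @param alternative \code{"greater"} (clustering) or \code{"two.sided"}.
#' @param seed integer seed.
#' @return A list of class \code{moran_result}: \code{I}, \code{p},
#'   \code{perm} (null values), \code{n}.
#' @export
morans_I <- function(values, grid_row, grid_col,
                     adjacency = c("rook", "queen"), n_perm = 100,
                     alternative = c("greater", "two.sided"), seed = 1) {
  adjacency <- match.arg(adjacency)
  alternative <- match.arg(alternative)
  ok <- is.finite(values)
  values <- values[ok]; grid_row <- grid_row[ok]; grid_col <- grid_col[ok]
  n <- length(values)
  if (n < 2) stop("need at least 2 finite values")
  if (stats::sd(values) == 0) stop("constant field: Moran's I undefined")
  W <- .moran_weights(grid_row, grid_col, adjacency)
  z <- values - mean(values)
  I_obs <- .moran_stat(z, W)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- vapply(seq_len(max(n_perm, 100)), function(i) {
    zp <- sample(z)
    .moran_stat(zp, W)
  }, 0)
  e0 <- -1 / (n - 1)
  p <- if (alternative == "greater")
    (1 + sum(perm >= I_obs)) / (length(perm) + 1)
  else
    (1 + sum(abs(perm - e0) >= abs(I_obs - e0))) / (length(perm) + 1)
  structure(list(I = I_obs, p = p, perm = perm, n = n,
                 adjacency = adjacency),
            class = "moran_result")
}

#' Moran's I averaged over electrode arrays
#'
#' Computes Moran's I within each array and averages, comparing the average
#' to a permutation null in which values are shuffled within each array.
#'
#' @param values per-site values.
#' @param site_meta data.frame with array_id, grid_row, grid_col.
#' @param ... passed to the per-array computation (adjacency).
#' @param n_perm permutations (default 100).
#' @param seed integer seed.
#' @return List: \code{I} (mean over arrays), \code{per_array}, \code{p},
#'   \code{n_perm}.
#' @export
morans_I_arrays <- function(values, site_meta, adjacency = "rook",
                            n_perm = 100, seed = 1) {
  arrays <- unique(site_meta$array_id)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pieces <- lapply(arrays, function(a) {
    idx <- which(site_meta$array_id == a & is.finite(values))
    if (length(idx) < 2 || stats::sd(values[idx]) == 0) return(NULL)
    W <- .moran_weights(site_meta$grid_row[idx], site_meta$grid_col[idx],
                        adjacency)
    z <- values[idx] - mean(values[idx])
    list(z = z, W = W, I = .moran_stat(z, W))
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0) stop("no array with enough finite values")
  I_arr <- vapply(pieces, `[[`, 0, "I")
  I_obs <- mean(I_arr)
  n_perm <- max(n_perm, 100)
  perm <- vapply(seq_len(n_perm), function(i)
    mean(vapply(pieces, function(p) .moran_stat(sample(p$z), p$W), 0)), 0)
  p <- (1 + sum(perm >= I_obs)) / (n_perm + 1)
  list(I = I_obs, per_array = I_arr, p = p, n_perm = n_perm)
}
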