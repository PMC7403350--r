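#' Simulation configuration for the synthetic neural population
#'
#' Defines the generative model for synthetic multi-unit sites with coarse
#' letter-by-position tuning, the statistical structure every downstream
#' analysis assumes.  Defaults follow the recorded-population conditions the
#' analyses were designed around: 510 sites, more than 30 repetitions per
#' image, a small (10\%) weakly word-selective subpopulation with realized
#' |d'| below 0.5, and spike-count-like (Poisson) repetition noise in a
#' 100 ms window.
#'
#' @param n_sites number of neural sites (default 510).
#' @param n_reps repetitions per stimulus (default 31; split-half analyses
#'   require at least 2).
#' @param tuning_sparsity in [0,1]; larger values concentrate a site's letter
#'   tuning on fewer letters (0 = near-uniform).
#' @param position_tolerance in [0,1]; the shared-variance fraction of a
#'   site's letter tuning across position slots (1 = identical tuning at
#'   every slot, 0 = independent tuning per slot); also lifts the floor of
#'   the position-envelope gain.
#' @param contralateral_bias multiplicative gain for slots contralateral to a
#'   site's hemisphere (default 1.5).
#' @param frac_word_selective fraction of sites given a lexical-class offset
#'   (default 0.10).
#' @param word_dprime_range absolute realized word-vs-pseudoword d' range for
#'   planted selective sites; must stay below 0.5 (weak selectivity).
#' @param mirror_symmetric_fraction fraction of sites whose letter tuning is
#'   built from horizontally mirror-invariant glyph features, so that
#'   mirror-image letters (e.g. b/d) drive them identically in expectation.
#' @param nonlinearity_weight weight in [0,1] of conjunctive adjacent
#'   letter-pair response terms (0 = perfectly linear letter summation).
#' @param noise_model \code{"poisson_like"} (variance of the spike count in
#'   the 100 ms window equals its mean) or \code{"gaussian"} (matched
#'   variance, analytically convenient).
#' @param baseline_rate,gain baseline firing rate and tuning gain in spikes/s.
#' @param window_ms spike-count window length (ms) used by the noise model.
#' @param variation_jitter_sd log-normal SD of per-(site, variation) gain
#'   modulation (case/size tolerance is high but not perfect).
#' @param seed integer seed; identical configs give identical tensors.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_sites = 510, n_reps = 31,
                       tuning_sparsity = 0.25, position_tolerance = 0.5,
                       contralateral_bias = 1.5,
                       frac_word_selective = 0.10,
                       word_dprime_range = c(0.15, 0.45),
                       mirror_symmetric_fraction = 0.1,
                       nonlinearity_weight = 0.2,
                       noise_model = c("poisson_like", "gaussian"),
                       baseline_rate = 10, gain = 20, window_ms = 100,
                       variation_jitter_sd = 0.08, seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_sites >= 1, n_reps >= 2,
            tuning_sparsity >= 0, tuning_sparsity <= 1,
            position_tolerance >= 0, position_tolerance <= 1,
            frac_word_selective >= 0, frac_word_selective <= 1,
            mirror_symmetric_fraction >= 0, mirror_symmetric_fraction <= 1,
            nonlinearity_weight >= 0, nonlinearity_weight <= 1,
            length(word_dprime_range) == 2,
            all(word_dprime_range >= 0), all(word_dprime_range < 0.5),
            word_dprime_range[1] <= word_dprime_range[2],
            baseline_rate > 0, gain >= 0, window_ms > 0)
  structure(as.list(environment()), class = "sim_config")
}

# 35-dimensional glyph-shape embedding of each lowercase letter; the
# mirror-symmetrized variant averages each glyph with its left-right flip,
# making embeddings of mirror-image letter pairs identical
.letter_embeddings <- function(font, symmetrize = FALSE) {
  E <- sapply(letters, function(l) {
    g <- font[[l]]
    if (symmetrize) g <- (g + g[, ncol(g):1]) / 2
    v <- as.numeric(g)
    (v - mean(v)) / max(stats::sd(v), 1e-12)
  })
  t(E)  # 26 x 35
}

.variation_index <- function(font_case, font_size) {
  match(paste(font_case, font_size),
        as.vector(outer(c("upper", "lower"), c("small", "medium", "large"),
                        paste)))
}

.noise_var_of_rate <- function(mu, cfg) mu / (cfg$window_ms / 1000)

.draw_rates <- function(mu, n_reps, cfg) {
  w <- cfg$window_ms / 1000
  n <- length(mu)
  if (cfg$noise_model == "poisson_like") {
    matrix(stats::rpois(n * n_reps, rep(mu, n_reps) * w) / w, nrow = n)
  } else {
    matrix(rep(mu, n_reps) +
             stats::rnorm(n * n_reps, 0, sqrt(rep(.noise_var_of_rate(mu, cfg),
                                                  n_reps))),
           nrow = n)
  }
}

#' Simulate a neural population response tensor
#'
#' Generates site x stimulus x repetition firing rates in two response
#' windows (70-170 ms and 170-270 ms after stimulus onset) plus per-trial
#' baseline rates.  Each site's expected rate to a string is
#' \deqn{baseline + gain [ \sum_k w(letter_k, k) + \lambda \sum conj ]}
#' with broad letter tuning \eqn{w} derived from glyph-shape features,
#' softened position tuning, contralateral gain, optional mirror-symmetric
#' tuning, and an additive lexical-class offset for a small planted
#' word-selective subpopulation, calibrated by root search so the realized
#' d' lands in the configured range.
#'
#' @param stimulus_set a \code{stimulus_set} with string and/or letter
#'   stimuli (see [build_base_set()], [build_letter_set()]).
#' @param config a [sim_config()].
#' @return A \code{response_tensor}: list with \code{rates} (sites x stimuli
#'   x reps x 2 windows), \code{baseline} (sites x stimuli x reps),
#'   \code{site_meta}, \code{stimulus_ids}, \code{stim_meta}, ground-truth
#'   \code{truth} (planted selective sites, offsets, expected rates), and
#'   the config.
#' @export
simulate_population <- function(stimulus_set, config = sim_config()) {
  stopifnot(inherits(stimulus_set, "stimulus_set"), inherits(config, "sim_config"))
  meta <- stimulus_set$meta
  n_stim <- nrow(meta)
  ns <- config$n_sites
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  font <- ortho_font("mono5x7")
  E_plain <- .letter_embeddings(font, symmetrize = FALSE)
  E_sym <- .letter_embeddings(font, symmetrize = TRUE)

  n_mirror <- round(config$mirror_symmetric_fraction * ns)
  is_mirror <- seq_len(ns) %in% sample.int(ns, n_mirror)

  # site letter tuning per slot: random projection of glyph embeddings,
  # positively rectified through exp(); beta controls tuning concentration.
  # Tuning at different slots shares a common component (weight =
  # position_tolerance) plus a slot-specific component, so letter tuning is
  # position-tolerant but not separable into letter x position factors.
  beta <- 3 * config$tuning_sparsity
  alpha <- config$position_tolerance
  nd <- ncol(E_plain)
  A0 <- matrix(stats::rnorm(ns * nd), ns)
  Ak <- lapply(1:4, function(k) matrix(stats::rnorm(ns * nd), ns))
  W <- array(0, c(ns, 26, 4), dimnames = list(NULL, LETTERS, NULL))
  for (s in seq_len(ns)) {
    e <- if (is_mirror[s]) E_sym else E_plain
    z0 <- as.numeric(A0[s, ] %*% t(e))
    z0 <- (z0 - mean(z0)) / max(stats::sd(z0), 1e-12)
    for (k in 1:4) {
      zk <- as.numeric(Ak[[k]][s, ] %*% t(e))
      zk <- (zk - mean(zk)) / max(stats::sd(zk), 1e-12)
      z <- sqrt(alpha) * z0 + sqrt(1 - alpha) * zk
      w <- exp(beta * z)
      W[s, , k] <- w / mean(w)
    }
  }

  # position tuning: gaussian bump around a preferred slot, floored by
  # position_tolerance, times hemisphere-contralateral gain (slots 1-2 are
  # contralateral for right-hemisphere sites, 3-4 for left)
  hemisphere <- rep(c("left", "right"), length.out = ns)
  pref <- sample.int(4, ns, replace = TRUE)
  floor_p <- 0.2 + 0.4 * config$position_tolerance
  P <- matrix(0, ns, 4)
  for (k in 1:4) {
    bump <- exp(-(k - pref)^2 / (2 * 0.5^2))
    P[, k] <- floor_p + (1 - floor_p) * bump
  }
  contra <- matrix(1, ns, 4)
  contra[hemisphere == "right", 1:2] <- config$contralateral_bias
  contra[hemisphere == "left", 3:4] <- config$contralateral_bias
  P <- P * contra
  P <- P / rowMeans(P)

  # conjunctive adjacent letter-pair terms: fixed random per site
  Cw <- config$nonlinearity_weight
  conj_coef <- if (Cw > 0) matrix(stats::rnorm(ns * 26 * 26 * 3, 0, 1), ns) else NULL

  # per-(site, variation) gain jitter and lognormal site-gain heterogeneity
  # (multi-unit sites differ widely in responsiveness)
  M <- matrix(exp(stats::rnorm(ns * 6, 0, config$variation_jitter_sd)), ns, 6)
  site_gain <- exp(stats::rnorm(ns, -0.125, 0.5))   # mean 1 on the raw scale

  vi <- .variation_index(meta$font_case, meta$font_size)
  is_string <- meta$lexical_class %in% c("word", "pseudoword")
  mu_sig <- matrix(0, ns, n_stim)   # tuning drive (before baseline/gain)
  for (j in seq_len(n_stim)) {
    if (is_string[j]) {
      ltr <- match(strsplit(meta$text[j], "")[[1]], LETTERS)
      drive <- rep(0, ns)
      for (k in 1:4) drive <- drive + W[, ltr[k], k] * P[, k]
      if (Cw > 0) {
        for (k in 1:3) {
          id <- (k - 1L) * 676L + (ltr[k + 1L] - 1L) * 26L + ltr[k]
          drive <- drive + Cw * conj_coef[, id]
        }
      }
      mu_sig[, j] <- drive
    } else {
      ltr <- match(meta$text[j], LETTERS)
      k <- meta$position_slot[j]
      mu_sig[, j] <- W[, ltr, k] * P[, k]
    }
  }
  mu <- config$baseline_rate +
    (config$gain * site_gain) * mu_sig * M[cbind(rep(seq_len(ns), n_stim),
                                                 rep(vi, each = ns))]
  mu <- pmax(mu, 0.1)

  # planted weakly word-selective subpopulation: additive offset on word
  # strings, calibrated so the realized d' (across stimuli, repetition-
  # averaged, including noise shrinkage) hits a drawn target
  n_sel <- round(config$frac_word_selective * ns)
  sel_sites <- if (n_sel > 0) sample.int(ns, n_sel) else integer(0)
  offsets <- numeric(ns)
  target_d <- numeric(ns)
  iw <- which(is_string & meta$lexical_class == "word")
  ip <- which(is_string & meta$lexical_class == "pseudoword")
  if (length(iw) >= 2 && length(ip) >= 2 && n_sel > 0) {
    tgt <- stats::runif(n_sel, config$word_dprime_range[1],
                        config$word_dprime_range[2]) *
      sample(c(-1, 1), n_sel, replace = TRUE)
    for (i in seq_len(n_sel)) {
      s <- sel_sites[i]
      vw <- stats::var(mu[s, iw]) + mean(.noise_var_of_rate(mu[s, iw], config)) / config$n_reps
      vp <- stats::var(mu[s, ip]) + mean(.noise_var_of_rate(mu[s, ip], config)) / config$n_reps
      dmu0 <- mean(mu[s, iw]) - mean(mu[s, ip])
      f <- function(d) (dmu0 + d) / sqrt((vw + vp) / 2) - tgt[i]
      offsets[s] <- stats::uniroot(f, interval = c(-1e4, 1e4))$root
      target_d[s] <- tgt[i]
      mu[s, iw] <- pmax(mu[s, iw] + offsets[s], 0.1)
    }
  }

  # draw repetitions: window 1 carries the full signal, window 2 a damped
  # copy with independent noise
  rates <- array(NA_real_, c(ns, n_stim, config$n_reps, 2),
                 dimnames = list(NULL, NULL, NULL, c("w70_170", "w170_270")))
  mu2 <- config$baseline_rate + 0.6 * (mu - config$baseline_rate)
  mu2 <- pmax(mu2, 0.1)
  rates[, , , 1] <- .draw_rates(as.numeric(mu), config$n_reps, config)
  rates[, , , 2] <- .draw_rates(as.numeric(mu2), config$n_reps, config)
  baseline <- array(.draw_rates(rep(config$baseline_rate, ns * n_stim),
                                config$n_reps, config),
                    c(ns, n_stim, config$n_reps))

  # electrode-array geometry: 10x10 grids, up to 96 sites per array
  n_arr <- ceiling(ns / 96)
  array_id <- rep(seq_len(n_arr), each = 96)[seq_len(ns)]
  grid_row <- integer(ns); grid_col <- integer(ns)
  for (a in seq_len(n_arr)) {
    idx <- which(array_id == a)
    pos <- sample.int(100, length(idx))
    grid_row[idx] <- (pos - 1L) %/% 10L
    grid_col[idx] <- (pos - 1L) %% 10L
  }
  site_meta <- data.frame(site_id = sprintf("site_%03d", seq_len(ns)),
                          array_id = array_id, grid_row = grid_row,
                          grid_col = grid_col, hemisphere = hemisphere,
                          stringsAsFactors = FALSE)

  structure(list(rates = rates, baseline = baseline,
                 window_labels = c("w70_170", "w170_270"),
                 site_meta = site_meta,
                 stimulus_ids = meta$stimulus_id, stim_meta = meta,
                 truth = list(selective_sites = sort(sel_sites),
                              offsets = offsets, target_dprime = target_d,
                              mirror_sites = which(is_mirror),
                              letter_tuning = W, position_tuning = P,
                              expected_rate = mu),
                 config = config, schema_version = "1.1"),
            class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat("response_tensor:", d[1], "sites x", d[2], "stimuli x", d[3],
      "reps x", d[4], "windows\n")
  invisible(x)
}

#' Combine two stimulus sets
#' @param a,b \code{stimulus_set} objects with disjoint stimulus ids.
#' @return A combined \code{stimulus_set}.
#' @export
c_stimulus_sets <- function(a, b) {
  .new_stimulus_set(c(a$images, b$images), rbind(a$meta, b$meta))
}

#' Simulate reference word-classification behavior
#'
#' Emulates a pool of subjects performing word/pseudoword classification
#' whose difficulty depends on orthographic typicality: the probability of a
#' "word" choice is a lapse-mixed logistic in lexical class and standardized
#' log mean bigram frequency.  The frequency slope acts mainly on
#' pseudowords (orthographically typical pseudowords draw false alarms), so
#' per-bin d' decreases with the bigram-frequency bin.  Subjects share the
#' generative parameters; trials are independent draws.
#'
#' @param stimulus_set a \code{stimulus_set} whose strings carry
#'   \code{mean_bigram_freq} metadata.
#' @param n_subjects number of subjects (default 6).
#' @param lapse lapse rate mixed uniformly into choices (default 0.02).
#' @param freq_slope logistic slope on standardized log bigram frequency
#'   (default 0.8; 0 gives a flat signature).
#' @param class_strength logistic offset separating words from pseudowords.
#' @param trials_per_stim trials per (subject, stimulus); at least 2 for
#'   split-half analyses.
#' @param seed integer seed.
#' @return A \code{data.frame} choice table with columns subject_id,
#'   stimulus_id, trial_index, choice ("word"/"pseudoword"), plus the true
#'   class and bigram frequency joined from the metadata.
#' @export
simulate_reference_behavior <- function(stimulus_set, n_subjects = 6,
                                        lapse = 0.02, freq_slope = 0.8,
                                        class_strength = 1.2,
                                        trials_per_stim = 40, seed = 1) {
  meta <- stimulus_set$meta
  meta <- meta[meta$lexical_class %in% c("word", "pseudoword"), , drop = FALSE]
  if (nrow(meta) == 0) stop("stimulus set contains no string stimuli")
  if (anyNA(meta$mean_bigram_freq)) stop("strings are missing bigram metadata")
  stopifnot(trials_per_stim >= 2, n_subjects >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  lbf <- log10(meta$mean_bigram_freq + 1)
  zbf <- if (stats::sd(lbf) > 0) (lbf - mean(lbf)) / stats::sd(lbf) else lbf * 0
  is_word <- meta$lexical_class == "word"
  eta <- ifelse(is_word, class_strength + 0.3 * freq_slope * zbf,
                -class_strength + freq_slope * zbf)
  p_word <- lapse / 2 + (1 - lapse) * stats::plogis(eta)

  n_stim <- nrow(meta)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ch <- stats::rbinom(n_stim * trials_per_stim, 1,
                        rep(p_word, each = trials_per_stim))
    out[[s]] <- data.frame(
      subject_id = sprintf("subject_%d", s),
      stimulus_id = rep(meta$stimulus_id, each = trials_per_stim),
      trial_index = rep(seq_len(trials_per_stim), n_stim),
      choice = ifelse(ch == 1, "word", "pseudoword"),
      lexical_class = rep(meta$lexical_class, each = trials_per_stim),
      mean_bigram_freq = rep(meta$mean_bigram_freq, each = trials_per_stim),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
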