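# Shared fixtures, built once per test run.  Sizes are deliberately small:
# the synthetic generator is exercised at full scale only where a test needs
# it.

fx <- new.env()

fx_config <- function() {
  if (is.null(fx$cfg)) fx$cfg <- stim_config(px_per_degree = 12)
  fx$cfg
}

# 20 + 20 strings under all 6 variations (240 images)
fx_base_set <- function() {
  if (is.null(fx$base))
    fx$base <- build_base_set(n_words = 20, n_pseudo = 20, seed = 7,
                              config = fx_config())
  fx$base
}

# full letter set: 26 letters x 4 positions x 6 variations
fx_letter_set <- function() {
  if (is.null(fx$letters)) fx$letters <- build_letter_set(config = fx_config())
  fx$letters
}

# combined tensor: 40 sites, 6 reps, default tuning
fx_tensor <- function() {
  if (is.null(fx$tensor)) {
    all <- c_stimulus_sets(fx_base_set(), fx_letter_set())
    fx$tensor <- simulate_population(all, sim_config(n_sites = 40, n_reps = 6,
                                                     seed = 11))
  }
  fx$tensor
}

# hand-built tiny response tensor for exact-arithmetic checks
fx_toy_tensor <- function(rates_array, baseline = NULL, stim_meta = NULL) {
  d <- dim(rates_array)
  structure(list(
    rates = rates_array,
    baseline = baseline,
    window_labels = dimnames(rates_array)[[4]],
    site_meta = data.frame(site_id = sprintf("site_%03d", seq_len(d[1])),
                           array_id = 1L, grid_row = seq_len(d[1]) - 1L,
                           grid_col = 0L, hemisphere = "left",
                           stringsAsFactors = FALSE),
    stimulus_ids = if (is.null(stim_meta)) sprintf("stim_%03d", seq_len(d[2]))
                   else stim_meta$stimulus_id,
    stim_meta = stim_meta, truth = NULL, config = NULL,
    schema_version = "1.1"), class = "response_tensor")
}

# choice table with deterministic per-stimulus choices repeated n times
fx_choice_table <- function(meta, p_word, n_trials, subject = "s1",
                            deterministic = FALSE, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    ch <- if (deterministic) rep(p_word[i] > 0.5, n_trials)
          else stats::rbinom(n_trials, 1, p_word[i]) == 1
    data.frame(subject_id = subject, stimulus_id = meta$stimulus_id[i],
               trial_index = seq_len(n_trials),
               choice = ifelse(ch, "word", "pseudoword"),
               lexical_class = meta$lexical_class[i],
               mean_bigram_freq = meta$mean_bigram_freq[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
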