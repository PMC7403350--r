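#' Pipeline run configuration
#'
#' Bundles every stage's parameters and seeds for an end-to-end run:
#' stimulus construction, population simulation, site screens, the decoding
#' battery, behavioral consistency, single-site statistics, encoding
#' reconstruction, and the mirror-symmetry analysis.  All seeds are
#' explicit so a manifest plus config regenerates every number.
#'
#' @param out_dir output directory.
#' @param n_words,n_pseudo base-set sizes.
#' @param px_per_degree stimulus raster resolution for this run.
#' @param sim a [sim_config()].
#' @param n_letter_tasks,n_bigram_tasks battery composition.
#' @param site_counts site-count sweep for word classification.
#' @param n_site_samples site samples per decode.
#' @param n_behavior_subjects,trials_per_stim reference-behavior scale.
#' @param stages character vector of stages to run.
#' @param force rerun stages whose outputs already exist.
#' @param seed master seed; per-stage seeds derive from it.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(out_dir = tempfile("orthopop_run_"),
                       n_words = 100, n_pseudo = 100, px_per_degree = 16,
                       sim = sim_config(n_sites = 120, n_reps = 10),
                       n_letter_tasks = 20, n_bigram_tasks = 8,
                       site_counts = c(10, 40, 120),
                       n_site_samples = 3,
                       n_behavior_subjects = 6, trials_per_stim = 20,
                       stages = c("stimuli", "simulate", "screen", "decode",
                                  "consistency", "single_site", "encoding",
                                  "mirror"),
                       force = FALSE, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

.stage_path <- function(cfg, name) file.path(cfg$out_dir, paste0(name, ".json"))

.write_stage <- function(cfg, name, obj) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(obj, .stage_path(cfg, name), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in dependency order on fully synthetic
#' data, writing one JSON result file per stage plus a manifest (config,
#' seeds, per-stage outputs and md5 hashes).  Completed stages are skipped
#' on rerun unless \code{force}; a failing stage stops with a diagnostic and
#' leaves earlier outputs in place.
#'
#' @param cfg a [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  scfg <- stim_config(px_per_degree = cfg$px_per_degree)
  done <- function(name) file.exists(.stage_path(cfg, name)) && !cfg$force
  state <- new.env()

  build_inputs <- function() {
    if (!is.null(state$tensor)) return(invisible())
    base <- build_base_set(n_words = cfg$n_words, n_pseudo = cfg$n_pseudo,
                           seed = cfg$seed, config = scfg)
    letters_set <- build_letter_set(config = scfg)
    state$base <- base
    state$letters <- letters_set
    state$all <- c_stimulus_sets(base, letters_set)
    state$tensor <- simulate_population(state$all, cfg$sim)
    state$features <- average_repetitions(state$tensor, "both_concatenated")
    state$features_early <- average_repetitions(state$tensor, "early_only")
  }

  if ("stimuli" %in% cfg$stages && !done("stimuli")) {
    build_inputs()
    m <- state$all$meta
    .write_stage(cfg, "stimuli", list(
      n_stimuli = nrow(m),
      n_string_images = sum(m$lexical_class != "letter"),
      n_letter_images = sum(m$lexical_class == "letter"),
      n_strings = length(unique(m$text[m$lexical_class != "letter"])),
      seed = cfg$seed))
    utils::write.csv(m, file.path(cfg$out_dir, "stimulus_meta.csv"),
                     row.names = FALSE)
  }
  if ("simulate" %in% cfg$stages && !done("simulate")) {
    build_inputs()
    .write_stage(cfg, "simulate", list(
      n_sites = cfg$sim$n_sites, n_reps = cfg$sim$n_reps,
      noise_model = cfg$sim$noise_model,
      n_planted_selective = length(state$tensor$truth$selective_sites),
      seed = cfg$sim$seed))
  }
  if ("screen" %in% cfg$stages && !done("screen")) {
    build_inputs()
    vd <- screen_visual_drive(state$tensor)
    lr <- screen_letter_reliability(state$tensor, seed = cfg$seed + 2)
    utils::write.csv(merge(vd, lr, by = "site_id"),
                     file.path(cfg$out_dir, "site_screens.csv"),
                     row.names = FALSE)
    .write_stage(cfg, "screen", list(
      n_visually_driven = sum(vd$visually_driven),
      n_reliable_letters = sum(lr$reliable_letters),
      n_total = nrow(vd)))
  }
  make_invariant <- function() {
    if (is.null(state$invariant))
      state$invariant <- subsample_invariant_set(
        state$base, n_words = min(40, cfg$n_words),
        n_pseudo = min(40, cfg$n_pseudo), n_variations = 5,
        seed = cfg$seed + 1)
    state$invariant
  }
  if ("decode" %in% cfg$stages && !done("decode")) {
    build_inputs()
    battery <- build_task_battery(state$base, make_invariant(),
                                  n_letter_tasks = cfg$n_letter_tasks,
                                  n_bigram_tasks = cfg$n_bigram_tasks)
    state$battery <- battery
    res <- lapply(battery, function(t)
      crossval_decode(state$features, t, n_site_samples = cfg$n_site_samples,
                      sites_per_sample = min(cfg$sim$n_sites,
                                             max(cfg$site_counts)),
                      seed = cfg$seed + 10))
    wc <- battery[[which(vapply(battery, `[[`, "", "task_id") ==
                           "word_classification_base")]]
    sweep_df <- site_count_sweep(state$features, wc, cfg$site_counts,
                                 n_site_samples = cfg$n_site_samples,
                                 seed = cfg$seed + 20)
    .write_stage(cfg, "decode", list(
      n_tasks = length(battery),
      tasks = lapply(res, function(r)
        list(task_id = r$task_id, accuracy = r$accuracy,
             accuracy_sd = r$accuracy_sd)),
      word_classification_sweep = sweep_df))
  }
  if ("consistency" %in% cfg$stages && !done("consistency")) {
    build_inputs()
    behav <- simulate_reference_behavior(
      state$base, n_subjects = cfg$n_behavior_subjects,
      trials_per_stim = cfg$trials_per_stim, seed = cfg$seed + 30)
    wc_task <- build_task_battery(state$base, make_invariant(),
                                  n_letter_tasks = 0,
                                  n_bigram_tasks = 0)[[1]]
    canon <- state$base$meta[state$base$meta$font_case == "upper" &
                               state$base$meta$font_size == "medium", ]
    dec_tab <- decoder_choice_table(state$features, wc_task, canon,
                                    n_repeats = 10, seed = cfg$seed + 31)
    behav_canon <- behav[behav$stimulus_id %in% canon$stimulus_id, ]
    cons <- consistency(dec_tab, behav_canon, seed = cfg$seed + 32)
    ceil <- pool_and_holdout_consistency(behav_canon, seed = cfg$seed + 33)
    .write_stage(cfg, "consistency", list(
      decoder_vs_pool_rho_tilde = cons$rho_tilde,
      ceiling_median = attr(ceil, "median"),
      ceiling_IQR = attr(ceil, "IQR"),
      per_subject = ceil))
  }
  if ("single_site" %in% cfg$stages && !done("single_site")) {
    build_inputs()
    m <- state$tensor$stim_meta
    canon <- m$lexical_class %in% c("word", "pseudoword") &
      m$font_case == "upper" & m$font_size == "medium"
    resp <- state$features_early$matrix[, canon, drop = FALSE]
    labs <- m$lexical_class[canon] == "word"
    sel <- site_selectivity_table(resp, labs, seed = cfg$seed + 40)
    frac_p <- selective_fraction_test(sum(sel$significant), nrow(sel))
    hemi_p <- if (sum(sel$significant) == 0) NA_real_ else
      hemisphere_bias_test(
        state$tensor$site_meta$hemisphere[sel$significant],
        mean(state$tensor$site_meta$hemisphere == "left"))
    mi <- tryCatch(morans_I_arrays(sel$dprime, state$tensor$site_meta,
                                   seed = cfg$seed + 41),
                   error = function(e) list(I = NA, p = NA))
    si_let <- vapply(seq_len(cfg$sim$n_sites), function(s)
      sparsity_index(rowMeans(site_category_responses(state$tensor, s,
                                                      "letters"))), 0)
    si_pos <- vapply(seq_len(cfg$sim$n_sites), function(s)
      sparsity_index(rowMeans(site_category_responses(state$tensor, s,
                                                      "positions"))), 0)
    utils::write.csv(sel, file.path(cfg$out_dir, "site_selectivity.csv"),
                     row.names = FALSE)
    .write_stage(cfg, "single_site", list(
      n_selective = sum(sel$significant), n_total = nrow(sel),
      selective_fraction_p = frac_p, hemisphere_bias_p = hemi_p,
      moran_I = mi$I, moran_p = mi$p,
      median_SI_letters = stats::median(si_let),
      median_SI_positions = stats::median(si_pos)))
  }
  if ("encoding" %in% cfg$stages && !done("encoding")) {
    build_inputs()
    n_enc <- min(cfg$sim$n_sites, 60)
    fits <- lapply(c("full_4", "best_3", "bag_of_letters"), function(mm)
      fit_reconstruction(state$tensor, model = mm, sites = seq_len(n_enc),
                         seed = cfg$seed + 50))
    names(fits) <- c("full_4", "best_3", "bag_of_letters")
    cmp <- compare_model_medians(fits$full_4, fits$bag_of_letters,
                                 seed = cfg$seed + 51)
    .write_stage(cfg, "encoding", list(
      medians = lapply(fits, function(f)
        stats::median(f$rho_tilde, na.rm = TRUE)),
      full4_vs_bag_p = cmp$p, n_sites = n_enc))
  }
  if ("mirror" %in% cfg$stages && !done("mirror")) {
    build_inputs()
    ms <- mirror_symmetry_analysis(state$tensor, config = scfg)
    utils::write.csv(ms$pairs, file.path(cfg$out_dir, "letter_pairs.csv"),
                     row.names = FALSE)
    .write_stage(cfg, "mirror", list(
      bin_summary = ms$bin_summary,
      p_rightmost = ms$p_rightmost, p_leftmost = ms$p_leftmost,
      p_right_vs_left = ms$p_right_vs_left))
  }

  files <- list.files(cfg$out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("orthopop")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = unclass(cfg[setdiff(names(cfg), "sim")]),
    sim_config = unclass(cfg$sim),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Reads the per-stage JSON outputs in a results directory and prints a
#' human-readable summary: task accuracies, consistency estimates,
#' selective-site fraction and its binomial p, sparsity medians,
#' reconstruction medians and mirror-symmetry bin statistics.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @return The collected stage results, invisibly.
#' @export
report <- function(results_dir) {
  if (!dir.exists(results_dir)) stop("no results directory: ", results_dir)
  stages <- c("stimuli", "simulate", "screen", "decode", "consistency",
              "single_site", "encoding", "mirror")
  got <- list()
  for (s in stages) {
    f <- file.path(results_dir, paste0(s, ".json"))
    if (file.exists(f)) got[[s]] <- jsonlite::fromJSON(f, simplifyVector = TRUE)
  }
  if (length(got) == 0) stop("no stage outputs found in ", results_dir)
  cat("== orthopop run report ==\n")
  if (!is.null(got$stimuli))
    cat(sprintf("stimuli: %d images (%d strings, %d letter images)\n",
                got$stimuli$n_stimuli, got$stimuli$n_string_images,
                got$stimuli$n_letter_images))
  if (!is.null(got$screen))
    cat(sprintf("screens: %d/%d visually driven, %d reliable letter tuning\n",
                got$screen$n_visually_driven, got$screen$n_total,
                got$screen$n_reliable_letters))
  if (!is.null(got$decode)) {
    cat(sprintf("decoding battery: %d tasks\n", got$decode$n_tasks))
    tk <- got$decode$tasks
    if (is.data.frame(tk)) {
      for (i in seq_len(nrow(tk)))
        cat(sprintf("  %-32s %.3f\n", tk$task_id[i], tk$accuracy[i]))
    } else {
      for (i in seq_along(tk))
        cat(sprintf("  %-32s %.3f\n", tk[[i]]$task_id, tk[[i]]$accuracy))
    }
  }
  if (!is.null(got$consistency))
    cat(sprintf("consistency: decoder-pool rho~ = %.3f (ceiling median %.3f)\n",
                got$consistency$decoder_vs_pool_rho_tilde,
                got$consistency$ceiling_median))
  if (!is.null(got$single_site))
    cat(sprintf(paste0("single sites: %d/%d selective (binomial p = %.2g), ",
                       "Moran's I = %.3f (p = %.2f), median SI letters %.2f ",
                       "positions %.2f\n"),
                got$single_site$n_selective, got$single_site$n_total,
                got$single_site$selective_fraction_p, got$single_site$moran_I,
                got$single_site$moran_p, got$single_site$median_SI_letters,
                got$single_site$median_SI_positions))
  if (!is.null(got$encoding))
    cat(sprintf("encoding: median rho~ full_4 %.2f, best_3 %.2f, bag %.2f (full>bag p = %.3g)\n",
                got$encoding$medians$full_4, got$encoding$medians$best_3,
                got$encoding$medians$bag_of_letters, got$encoding$full4_vs_bag_p))
  if (!is.null(got$mirror))
    cat(sprintf("mirror symmetry: right-vs-left bin p = %.3g\n",
                got$mirror$p_right_vs_left))
  invisible(got)
}
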