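test_that("rendering is deterministic and geometrically calibrated", {
  cfg <- stim_config(px_per_degree = 32)
  a <- render_string("A", "upper", "large", cfg)
  b <- render_string("A", "upper", "large", cfg)
  expect_identical(a$pixels, b$pixels)

  # a four-letter small string spans ~3.2 degrees, within one glyph advance
  img <- render_string("WORD", "upper", "small", cfg)
  width <- img$bbox["col_max"] - img$bbox["col_min"] + 1
  adv <- round(0.8 * 32)
  expect_lt(abs(width - 3.2 * 32), adv)

  expect_error(render_string("W0RD", "upper", "small", cfg), "alphabetic")
  expect_error(render_string("WORDS", "upper", "small", cfg), "alphabetic")
})

test_that("mirror-exact face renders b and d as exact horizontal mirrors", {
  cfg <- stim_config(px_per_degree = 16, font = "mirror")
  b <- render_string("b", "lower", "medium", cfg)
  d <- render_string("d", "lower", "medium", cfg)
  bb <- b$bbox
  crop_b <- b$pixels[bb["row_min"]:bb["row_max"], bb["col_min"]:bb["col_max"]]
  dd <- d$bbox
  crop_d <- d$pixels[dd["row_min"]:dd["row_max"], dd["col_min"]:dd["col_max"]]
  expect_identical(crop_d, crop_b[, ncol(crop_b):1])
})

test_that("base set obeys the count and pseudoword-construction rules", {
  base <- fx_base_set()
  expect_equal(nrow(base$meta), 40 * 6)
  expect_false(anyDuplicated(base$meta$stimulus_id) > 0)

  one <- build_base_set(n_words = 1, n_pseudo = 0, seed = 1,
                        config = fx_config())
  expect_equal(length(one$images), 6)

  pseudos <- unique(base$meta$text[base$meta$lexical_class == "pseudoword"])
  n_vowels <- vapply(strsplit(pseudos, ""),
                     function(ch) sum(ch %in% c("A", "E", "I", "O", "U")), 0L)
  expect_true(all(n_vowels == 1))
  expect_true(all(nchar(pseudos) == 4))

  # reproducible under seed
  again <- build_base_set(n_words = 20, n_pseudo = 20, seed = 7,
                          config = fx_config())
  expect_identical(base$meta, again$meta)

  expect_error(build_base_set(word_list = c("ab", "abcd"), n_words = 5,
                              config = fx_config()), "word list")
})

test_that("letter set covers letters x positions x variations with slot layout", {
  lets <- fx_letter_set()
  expect_equal(nrow(lets$meta), 26 * 4 * 6)
  expect_false(anyDuplicated(lets$meta$stimulus_id) > 0)
  expect_true(all(lets$meta$position_slot %in% 1:4))

  tiny <- build_letter_set(alphabet = "A", positions = 1, variations = 1,
                           config = fx_config())
  expect_equal(length(tiny$images), 1)

  # a slot-k letter's foreground lies inside slot k's column band
  cfg <- fx_config()
  img <- render_string("H", "upper", "medium", cfg, position_slot = 3)
  adv <- round(1.2 * cfg$px_per_degree)
  x0 <- floor((cfg$canvas_px - 4 * adv) / 2)
  expect_gte(img$bbox["col_min"], x0 + 2 * adv)
  expect_lte(img$bbox["col_max"], x0 + 3 * adv)
})

test_that("mean bigram frequency averages adjacent ordered bigrams", {
  tb <- c(TH = 100, HE = 50, EX = 10)
  expect_equal(mean_bigram_frequency("THEX", tb), (100 + 50 + 10) / 3)
  expect_equal(mean_bigram_frequency("QZQZ", tb), 0)   # missing bigrams are 0
  expect_error(mean_bigram_frequency("A", tb), "at least 2")

  # packaged table produces a broad spread over rule-conforming pseudowords
  set.seed(3)
  pw <- orthopop:::.generate_pseudowords(300)
  freqs <- vapply(pw, mean_bigram_frequency, 0)
  expect_gt(stats::IQR(freqs), 0)
  expect_gt(stats::sd(freqs), 0)
})

test_that("reflectivity is a symmetric IoU in [0,1] with exact mirror pairs", {
  cfg <- stim_config(px_per_degree = 16, font = "mirror")
  b <- render_string("b", "lower", "medium", cfg)
  d <- render_string("d", "lower", "medium", cfg)
  expect_equal(reflectivity(b, d, "horizontal"), 1)
  rv <- reflectivity(b, d, "vertical")
  expect_lt(rv, 1)

  # explicit pixel-count verification of R_V for the fixture pair
  flip_v <- function(img) {
    bb <- img$bbox
    crop <- img$pixels[bb["row_min"]:bb["row_max"],
                       bb["col_min"]:bb["col_max"], drop = FALSE]
    crop[nrow(crop):1, , drop = FALSE]
  }
  ca <- {
    bb <- b$bbox
    b$pixels[bb["row_min"]:bb["row_max"], bb["col_min"]:bb["col_max"]]
  }
  cb <- flip_v(d)
  # same bbox sizes here, so centre alignment is the identity overlay
  inter <- sum(ca & cb); uni <- sum(ca | cb)
  expect_equal(rv, inter / uni)

  # self-mirror-symmetric glyph: R_H with itself is 1
  o <- render_string("O", "upper", "medium", cfg)
  expect_equal(reflectivity(o, o, "horizontal"), 1)

  # symmetry in arguments, range, for several pairs
  li <- render_letter_images(c("A", "B", "J", "L", "N", "U"),
                             font_case = "upper", config = fx_config())
  for (i in 1:5) for (j in (i + 1):6) {
    for (ax in c("horizontal", "vertical")) {
      r1 <- reflectivity(li[[i]], li[[j]], ax)
      r2 <- reflectivity(li[[j]], li[[i]], ax)
      expect_identical(r1, r2)
      expect_gte(r1, 0); expect_lte(r1, 1)
    }
  }
})

test_that("double reflection of a mask is the identity", {
  img <- render_string("G", "upper", "medium", fx_config())
  flip_h <- function(m) m[, ncol(m):1, drop = FALSE]
  expect_identical(flip_h(flip_h(img$pixels)), img$pixels)
  flip_v <- function(m) m[nrow(m):1, , drop = FALSE]
  expect_identical(flip_v(flip_v(img$pixels)), img$pixels)
})

test_that("pairwise reflectivity records cover all unordered distinct pairs", {
  li3 <- render_letter_images(c("A", "B", "C"), config = fx_config())
  rec <- all_letter_pair_reflectivity(li3)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$delta_R, rec$R_H - rec$R_V)
  expect_true(all(rec$letter_a != rec$letter_b))
  expect_error(all_letter_pair_reflectivity(unname(li3)), "named")
})
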