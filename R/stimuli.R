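#' Stimulus rendering configuration
#'
#' Controls the pixel geometry of rendered orthographic stimuli.  Letters are
#' specified in degrees of visual angle and converted to pixels through
#' \code{px_per_degree}.  The canvas spans \code{canvas_deg} degrees (the full
#' image frame within which strings and letters are centred).
#'
#' @param px_per_degree pixels per degree of visual angle (default 32).
#' @param canvas_deg canvas side length in degrees (default 8).
#' @param font bitmap font face, see [ortho_font()].
#' @param sizes named numeric vector giving letter heights in degrees for the
#'   three size variations.  Strings of four letters span four times the
#'   letter size because inter-letter spacing is proportional to letter size.
#' @return A list of class \code{"stim_config"}.
#' @export
stim_config <- function(px_per_degree = 32, canvas_deg = 8,
                        font = "mono5x7",
                        sizes = c(small = 0.8, medium = 1.2, large = 1.6)) {
  stopifnot(px_per_degree > 0, canvas_deg > 0,
            all(c("small", "medium", "large") %in% names(sizes)))
  structure(list(px_per_degree = px_per_degree,
                 canvas_deg = canvas_deg,
                 canvas_px = as.integer(round(px_per_degree * canvas_deg)),
                 font_name = font,
                 font = ortho_font(font),
                 sizes = sizes),
            class = "stim_config")
}

.resize_mask <- function(glyph, h, w) {
  # pixel-centre sampling: commutes with horizontal/vertical flips, so a
  # mirror-image glyph pair stays an exact mirror pair at any raster size
  ri <- pmin(nrow(glyph), pmax(1L, floor((seq_len(h) - 0.5) / h * nrow(glyph)) + 1L))
  ci <- pmin(ncol(glyph), pmax(1L, floor((seq_len(w) - 0.5) / w * ncol(glyph)) + 1L))
  glyph[ri, ci, drop = FALSE]
}

.mask_bbox <- function(px) {
  fg <- which(px != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("glyph image has no foreground pixels")
  c(row_min = min(fg[, 1]), row_max = max(fg[, 1]),
    col_min = min(fg[, 2]), col_max = max(fg[, 2]))
}

.new_glyph_image <- function(px, letter_height_px) {
  structure(list(pixels = px,
                 canvas_size = nrow(px),
                 letter_height_px = letter_height_px,
                 bbox = .mask_bbox(px)),
            class = "glyph_image")
}

#' Render a letter string as a binary glyph image
#'
#' Strings are drawn in a monospaced bitmap font on a square canvas.  Each
#' letter occupies a slot whose width equals the letter height (so a
#' four-letter string spans four times the single-letter visual angle, with
#' spacing proportional to letter size).  Single letters can be placed in one
#' of the four string slots via \code{position_slot}.
#'
#' @param text a 1-4 character alphabetic string.
#' @param font_case \code{"upper"} or \code{"lower"}.
#' @param font_size \code{"small"}, \code{"medium"} or \code{"large"}
#'   (0.8, 1.2, 1.6 degrees per letter by default).
#' @param config a [stim_config()].
#' @param position_slot for single letters, the slot (1-4) of the four-slot
#'   string layout where the letter is placed; \code{NULL} centres the text.
#' @return A \code{glyph_image}: binary pixel matrix plus bounding box.
#' @export
render_string <- function(text, font_case = c("upper", "lower"),
                          font_size = c("medium", "small", "large"),
                          config = stim_config(), position_slot = NULL) {
  font_case <- match.arg(font_case)
  font_size <- match.arg(font_size)
  if (!is.character(text) || length(text) != 1 || nchar(text) < 1 ||
      nchar(text) > 4 || !grepl("^[A-Za-z]+$", text))
    stop("'text' must be a 1-4 character alphabetic string")
  shown <- if (font_case == "upper") toupper(text) else tolower(text)
  chars <- strsplit(shown, "")[[1]]
  n <- length(chars)

  h <- as.integer(round(config$sizes[[font_size]] * config$px_per_degree))
  if (h < 7) stop("px_per_degree too small: letter height below glyph grid")
  adv <- h                                   # slot width equals letter height
  gw <- as.integer(round(h * 5 / 7))         # glyph ink width within its slot
  cs <- config$canvas_px
  px <- matrix(0L, cs, cs)

  n_slots <- if (is.null(position_slot)) n else 4L
  layout_w <- n_slots * adv
  x0 <- floor((cs - layout_w) / 2)
  y0 <- floor((cs - h) / 2)
  if (x0 < 0 || y0 < 0) stop("canvas too small for requested string")

  slots <- if (is.null(position_slot)) seq_len(n) else {
    stopifnot(length(position_slot) == 1, position_slot %in% 1:4, n == 1)
    as.integer(position_slot)
  }
  for (i in seq_len(n)) {
    g <- config$font[[chars[i]]]
    if (is.null(g)) stop("glyph missing from font: ", chars[i])
    m <- .resize_mask(g, h, gw)
    sx <- x0 + (slots[i] - 1L) * adv + floor((adv - gw) / 2)
    px[(y0 + 1):(y0 + h), (sx + 1):(sx + gw)] <-
      pmax(px[(y0 + 1):(y0 + h), (sx + 1):(sx + gw)], m)
  }
  .new_glyph_image(px, h)
}

#' Packaged bigram frequency table
#'
#' Counts-per-million for all 676 ordered letter bigrams, computed once from
#' the packaged four-letter word list and frozen in the package.  A string's
#' mean bigram frequency indexes its orthographic typicality and is the
#' binning variable for behavioral signatures.
#'
#' @return A named numeric vector of length 676 (names \code{"AA"}..\code{"ZZ"}).
#' @export
ortho_bigram_table <- function() {
  path <- system.file("extdata", "bigram_freq.tsv", package = "orthopop")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$count_per_million, df$bigram)
}

#' Packaged four-letter English word list
#' @return Character vector of lowercase four-letter words.
#' @export
ortho_words <- function() {
  readLines(system.file("extdata", "fourletter_words.txt", package = "orthopop"))
}

#' Mean bigram frequency of a string
#'
#' Arithmetic mean of the counts-per-million frequencies of the adjacent
#' ordered bigrams of \code{text} (three bigrams for a four-letter string).
#' Bigrams missing from the table count as zero.
#'
#' @param text string of length >= 2 (case-insensitive).
#' @param bigram_table named vector as from [ortho_bigram_table()].
#' @return Mean frequency in counts per million.
#' @export
mean_bigram_frequency <- function(text, bigram_table = ortho_bigram_table()) {
  text <- toupper(text)
  n <- nchar(text)
  if (n < 2) stop("'text' must have at least 2 characters")
  bgs <- vapply(seq_len(n - 1), function(i) substr(text, i, i + 1), "")
  f <- bigram_table[bgs]
  f[is.na(f)] <- 0
  mean(f)
}

.VOWELS <- c("A", "E", "I", "O", "U")

#' Generate pseudowords (one vowel, three consonants)
#'
#' Pseudowords mimic the letter statistics of real words: the vowel and the
#' consonant at each position are drawn from the position-specific letter
#' distributions of \code{letter_source} (typically the sampled words), so
#' that words and pseudowords differ in letter combinations rather than in
#' marginal letter frequencies.  Each pseudoword contains exactly one vowel
#' ("y" counts as a consonant).
#'
#' @param n number of pseudowords.
#' @param exclude words (any case) the pseudowords must not collide with.
#' @param letter_source uppercase four-letter strings supplying the
#'   position-wise letter pools; NULL falls back to uniform letters.
#' @return Character vector of unique uppercase four-letter pseudowords.
#' @keywords internal
.generate_pseudowords <- function(n, exclude = character(),
                                  letter_source = NULL) {
  consonants <- setdiff(LETTERS, .VOWELS)
  excl <- toupper(exclude)
  vpool <- .VOWELS
  vpos_pool <- 1:4
  cpool <- rep(list(consonants), 4)
  if (!is.null(letter_source) && length(letter_source) > 0) {
    lm <- do.call(rbind, strsplit(toupper(letter_source), ""))
    v <- lm[lm %in% .VOWELS]
    if (length(v) > 0) vpool <- v
    vp <- which(lm %in% .VOWELS, arr.ind = FALSE)
    vp <- ((vp - 1) %/% nrow(lm)) + 1   # column (= slot) of each vowel
    if (length(vp) > 0) vpos_pool <- vp
    for (k in 1:4) {
      ck <- lm[, k][lm[, k] %in% consonants]
      if (length(ck) > 0) cpool[[k]] <- ck
    }
  }
  out <- character(0)
  guard <- 0
  while (length(out) < n) {
    guard <- guard + 1
    if (guard > 200 * n + 1000) stop("pseudoword generation failed to converge")
    vpos <- sample(vpos_pool, 1)
    ch <- vapply(1:4, function(k) sample(cpool[[k]], 1), "")
    ch[vpos] <- sample(vpool, 1)
    pw <- paste(ch, collapse = "")
    if (!(pw %in% out) && !(pw %in% excl)) out <- c(out, pw)
  }
  out
}

.render_variations <- function(texts, classes, config, bigram_table) {
  cases <- c("upper", "lower")
  sizes <- c("small", "medium", "large")
  images <- vector("list", length(texts) * 6)
  meta <- vector("list", length(texts) * 6)
  k <- 0
  for (i in seq_along(texts)) {
    bf <- mean_bigram_frequency(texts[i], bigram_table)
    for (cs in cases) for (sz in sizes) {
      k <- k + 1
      images[[k]] <- render_string(texts[i], font_case = cs, font_size = sz,
                                   config = config)
      meta[[k]] <- data.frame(
        stimulus_id = sprintf("str_%s_%s_%s", toupper(texts[i]), cs, sz),
        text = toupper(texts[i]), lexical_class = classes[i],
        font_case = cs, font_size = sz, position_slot = NA_integer_,
        mean_bigram_freq = bf, stringsAsFactors = FALSE)
    }
  }
  list(images = images, meta = do.call(rbind, meta))
}

.new_stimulus_set <- function(images, meta) {
  stopifnot(length(images) == nrow(meta), !anyDuplicated(meta$stimulus_id))
  rownames(meta) <- NULL
  structure(list(images = images, meta = meta), class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("stimulus_set:", nrow(x$meta), "stimuli (",
      sum(x$meta$lexical_class == "word"), "word /",
      sum(x$meta$lexical_class == "pseudoword"), "pseudoword /",
      sum(x$meta$lexical_class == "letter"), "letter images )\n")
  invisible(x)
}

#' Build the base string stimulus set
#'
#' Samples \code{n_words} four-letter words from the packaged word list and
#' generates \code{n_pseudo} pseudowords (exactly one vowel and three
#' consonants), then renders each string under all six variations
#' (3 sizes x 2 cases).  With the default 308 + 308 strings this yields 3696
#' images.
#'
#' @param word_list candidate words; defaults to the packaged list.
#' @param n_words,n_pseudo numbers of words and pseudowords (defaults 308 each).
#' @param seed integer seed; the set is fully reproducible.
#' @param config a [stim_config()].
#' @param bigram_table table for the per-string mean bigram frequency.
#' @param match_letter_stats when TRUE (default), words are restricted to
#'   one-vowel words and pseudoword letters are drawn from the words'
#'   position-specific letter distributions, so the two classes match in
#'   marginal letter statistics and differ in letter combinations — the
#'   regime in which single sites are at most weakly class-selective.
#' @return A \code{stimulus_set} (parallel image list and metadata frame).
#' @export
build_base_set <- function(word_list = ortho_words(), n_words = 308,
                           n_pseudo = 308, seed = 1,
                           config = stim_config(),
                           bigram_table = ortho_bigram_table(),
                           match_letter_stats = TRUE) {
  word_list <- word_list[nchar(word_list) == 4 & grepl("^[A-Za-z]+$", word_list)]
  if (match_letter_stats) {
    nv <- vapply(strsplit(toupper(word_list), ""),
                 function(ch) sum(ch %in% .VOWELS), 0L)
    word_list <- word_list[nv == 1]
  }
  if (length(word_list) < n_words)
    stop("word list has only ", length(word_list), " four-letter words; ",
         n_words, " requested")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  words <- toupper(sample(word_list, n_words))
  pseudos <- .generate_pseudowords(
    n_pseudo, exclude = word_list,
    letter_source = if (match_letter_stats) words else NULL)
  texts <- c(words, pseudos)
  classes <- rep(c("word", "pseudoword"), c(n_words, n_pseudo))
  rv <- .render_variations(texts, classes, config, bigram_table)
  .new_stimulus_set(rv$images, rv$meta)
}

#' Build the single-letter stimulus set
#'
#' One image per (letter, position slot, case x size variation).  Position
#' slots are the four letter slots of the four-letter string layout, so that
#' single-letter responses can serve as predictors for string responses.
#' The full default set is 26 letters x 4 positions x 6 variations = 624
#' stimuli.
#'
#' @param alphabet letters to render (default A-Z).
#' @param positions number of position slots (default 4).
#' @param variations number of case x size variations to use, in the fixed
#'   order upper/lower crossed with small/medium/large (default 6 = all).
#' @param config a [stim_config()].
#' @return A \code{stimulus_set}.
#' @export
build_letter_set <- function(alphabet = LETTERS, positions = 4, variations = 6,
                             config = stim_config()) {
  stopifnot(length(alphabet) >= 1, positions >= 1, positions <= 4,
            variations >= 1, variations <= 6)
  var_grid <- expand.grid(font_size = c("small", "medium", "large"),
                          font_case = c("upper", "lower"),
                          stringsAsFactors = FALSE)
  # canonical variation (upper, medium) first
  ord <- order(var_grid$font_case != "upper", var_grid$font_size != "medium")
  var_grid <- var_grid[ord, ][seq_len(variations), , drop = FALSE]
  images <- list(); meta <- list(); k <- 0
  for (L in toupper(alphabet)) for (p in seq_len(positions)) {
    for (v in seq_len(nrow(var_grid))) {
      k <- k + 1
      cs <- var_grid$font_case[v]; sz <- var_grid$font_size[v]
      images[[k]] <- render_string(L, font_case = cs, font_size = sz,
                                   config = config, position_slot = p)
      meta[[k]] <- data.frame(
        stimulus_id = sprintf("let_%s_p%d_%s_%s", L, p, cs, sz),
        text = L, lexical_class = "letter", font_case = cs, font_size = sz,
        position_slot = p, mean_bigram_freq = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  .new_stimulus_set(images, do.call(rbind, meta))
}

.fg_coords <- function(img) {
  fg <- which(img$pixels != 0, arr.ind = TRUE)
  b <- img$bbox
  # centred half-pixel coordinates: reflection about the bounding-box centre
  # is exact negation, so alignment and parity are handled without rounding
  cbind(r = 2L * fg[, 1] - (b["row_min"] + b["row_max"]),
        c = 2L * fg[, 2] - (b["col_min"] + b["col_max"]))
}

#' Pixel reflectivity between two glyph images
#'
#' Reflects the second glyph about the centre of its own bounding box along
#' the requested axis, aligns the two bounding-box centres, and returns the
#' intersection-over-union of foreground pixels.  \code{"horizontal"} means a
#' left-right mirror flip (sensitivity to pairs like b/d); \code{"vertical"}
#' an up-down flip (pairs like b/p).  The measure is symmetric in its two
#' arguments and lies in [0, 1].
#'
#' @param img_a,img_b \code{glyph_image} objects with non-empty foreground.
#' @param axis \code{"horizontal"} or \code{"vertical"}.
#' @return IoU overlap in [0, 1].
#' @export
reflectivity <- function(img_a, img_b, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  A <- .fg_coords(img_a)
  B <- .fg_coords(img_b)
  if (axis == "horizontal") B[, "c"] <- -B[, "c"] else B[, "r"] <- -B[, "r"]
  ka <- paste(A[, 1], A[, 2])
  kb <- paste(B[, 1], B[, 2])
  inter <- length(intersect(ka, kb))
  inter / (nrow(A) + nrow(B) - inter)
}

#' Reflectivity records for all letter pairs
#'
#' Computes horizontal and vertical reflectivity and their difference
#' \eqn{\Delta R = R_H - R_V} for every unordered pair of distinct letters.
#' Identity pairs are excluded (alphabet letters are biased towards
#' horizontal self-symmetry, which would inflate the mirror-symmetry
#' evidence).  26 letters give choose(26, 2) = 325 records.
#'
#' @param letter_images named list of \code{glyph_image}s at a common case
#'   and size, names = letters.
#' @return A data.frame with columns letter_a, letter_b, R_H, R_V, delta_R.
#' @export
all_letter_pair_reflectivity <- function(letter_images) {
  nm <- names(letter_images)
  if (is.null(nm) || anyDuplicated(nm))
    stop("letter_images must be a named list with unique letter names")
  n <- length(nm)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    rh <- reflectivity(letter_images[[i]], letter_images[[j]], "horizontal")
    rv <- reflectivity(letter_images[[i]], letter_images[[j]], "vertical")
    out[[k]] <- data.frame(letter_a = nm[i], letter_b = nm[j],
                           R_H = rh, R_V = rv, delta_R = rh - rv,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Render one image per letter at a fixed case/size
#'
#' Convenience for reflectivity analyses: letters rendered alone (no slot
#' layout), so reflectivity depends only on glyph shape.
#'
#' @inheritParams build_letter_set
#' @param font_case,font_size the common variation.
#' @return Named list of \code{glyph_image}s.
#' @export
render_letter_images <- function(alphabet = LETTERS, font_case = "lower",
                                 font_size = "medium", config = stim_config()) {
  stats::setNames(lapply(alphabet, function(L)
    render_string(L, font_case = font_case, font_size = font_size,
                  config = config)), alphabet)
}

# save/restore the global RNG state so seeded constructors do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
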