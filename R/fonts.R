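#' Built-in monospaced bitmap fonts
#'
#' The package renders all orthographic stimuli from a compact monospaced
#' bitmap font defined directly in code, so that rendering is bit-exact,
#' deterministic, and free of any system font dependency.  Two faces are
#' available:
#' \describe{
#'   \item{\code{"mono5x7"}}{the default face: every letter (upper and lower
#'     case) on a 5 x 7 cell grid, in the style of classic terminal fonts.}
#'   \item{\code{"mirror"}}{identical to \code{"mono5x7"} except that the
#'     glyphs \code{d}, \code{p} and \code{q} (both cases) are constructed as
#'     exact horizontal / vertical / double reflections of \code{b}.  This
#'     face exists so that mirror-symmetry computations can be verified
#'     against pairs that are reflections by construction.}
#' }
#'
#' @param name face name, \code{"mono5x7"} or \code{"mirror"}.
#' @return A named list of 0/1 integer matrices (7 rows x 5 columns), one per
#'   glyph, with names \code{"A"}..\code{"Z"} and \code{"a"}..\code{"z"}.
#' @examples
#' f <- ortho_font()
#' dim(f$A)
#' @export
ortho_font <- function(name = c("mono5x7", "mirror")) {
  name <- match.arg(name)
  f <- .font_mono5x7()
  if (name == "mirror") {
    f$d <- f$b[, ncol(f$b):1]
    f$p <- f$b[nrow(f$b):1, ]
    f$q <- f$b[nrow(f$b):1, ncol(f$b):1]
    f$D <- f$B[, ncol(f$B):1]
    f$P <- f$B[nrow(f$B):1, ]
    f$Q <- f$B[nrow(f$B):1, ncol(f$B):1]
  }
  f
}

.parse_glyph <- function(rows) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), function(ch) as.integer(ch == "#")))
  storage.mode(m) <- "integer"
  m
}

.font_mono5x7 <- function() {
  g <- .font_glyph_strings()
  out <- lapply(g, .parse_glyph)
  out
}

.font_glyph_strings <- function() {
  list(
    A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    B = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
    C = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
    D = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
    E = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
    F = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
    G = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
    H = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    I = c(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
    J = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
    K = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
    L = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
    M = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
    N = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
    O = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    P = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
    Q = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
    R = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
    S = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
    T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    U = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    V = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
    W = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
    X = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
    Y = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
    Z = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
    a = c(".....", ".....", ".###.", "....#", ".####", "#...#", ".####"),
    b = c("#....", "#....", "####.", "#...#", "#...#", "#...#", "####."),
    c = c(".....", ".....", ".###.", "#....", "#....", "#...#", ".###."),
    d = c("....#", "....#", ".####", "#...#", "#...#", "#...#", ".####"),
    e = c(".....", ".....", ".###.", "#...#", "#####", "#....", ".###."),
    f = c("..##.", ".#..#", ".#...", "###..", ".#...", ".#...", ".#..."),
    g = c(".....", ".####", "#...#", "#...#", ".####", "....#", ".###."),
    h = c("#....", "#....", "####.", "#...#", "#...#", "#...#", "#...#"),
    i = c("..#..", ".....", ".##..", "..#..", "..#..", "..#..", ".###."),
    j = c("...#.", ".....", "..##.", "...#.", "...#.", "#..#.", ".##.."),
    k = c("#....", "#....", "#..#.", "#.#..", "##...", "#.#..", "#..#."),
    l = c(".##..", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
    m = c(".....", ".....", "##.#.", "#.#.#", "#.#.#", "#.#.#", "#.#.#"),
    n = c(".....", ".....", "####.", "#...#", "#...#", "#...#", "#...#"),
    o = c(".....", ".....", ".###.", "#...#", "#...#", "#...#", ".###."),
    p = c(".....", "####.", "#...#", "#...#", "####.", "#....", "#...."),
    q = c(".....", ".####", "#...#", "#...#", ".####", "....#", "....#"),
    r = c(".....", ".....", "#.##.", "##..#", "#....", "#....", "#...."),
    s = c(".....", ".....", ".####", "#....", ".###.", "....#", "####."),
    t = c(".#...", ".#...", "###..", ".#...", ".#...", ".#..#", "..##."),
    u = c(".....", ".....", "#...#", "#...#", "#...#", "#...#", ".####"),
    v = c(".....", ".....", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
    w = c(".....", ".....", "#...#", "#...#", "#.#.#", "#.#.#", ".#.#."),
    x = c(".....", ".....", "#...#", ".#.#.", "..#..", ".#.#.", "#...#"),
    y = c(".....", "#...#", "#...#", "#...#", ".####", "....#", ".###."),
    z = c(".....", ".....", "#####", "...#.", "..#..", ".#...", "#####")
  )
}
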