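#' Write a response tensor to disk
#'
#' Serializes a \code{response_tensor} as a sidecar directory of plain-text
#' files: a JSON header (schema version, dimensions, window labels, config),
#' rates and baseline tables at full double precision, site metadata and
#' stimulus ids.  The round-trip is lossless (bit-identical rates).
#'
#' @param tensor a \code{response_tensor}.
#' @param path directory to create (must not already contain a tensor unless
#'   \code{overwrite = TRUE}).
#' @param overwrite replace an existing container.
#' @return \code{path}, invisibly.
#' @export
write_tensor <- function(tensor, path, overwrite = FALSE) {
  stopifnot(inherits(tensor, "response_tensor"))
  if (dir.exists(path) && file.exists(file.path(path, "header.json")) &&
      !overwrite)
    stop("tensor container already exists at ", path)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(tensor$rates)
  header <- list(schema_version = "1.1", container = "orthopop_tensor",
                 dims = as.list(stats::setNames(d, c("sites", "stimuli",
                                                    "reps", "windows"))),
                 window_labels = tensor$window_labels,
                 has_baseline = !is.null(tensor$baseline))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, pretty = TRUE),
             file.path(path, "header.json"))
  writeLines(sprintf("%.17g", as.numeric(tensor$rates)),
             file.path(path, "rates.txt"))
  if (!is.null(tensor$baseline))
    writeLines(sprintf("%.17g", as.numeric(tensor$baseline)),
               file.path(path, "baseline.txt"))
  utils::write.csv(tensor$site_meta, file.path(path, "site_meta.csv"),
                   row.names = FALSE)
  writeLines(tensor$stimulus_ids, file.path(path, "stimulus_ids.txt"))
  if (!is.null(tensor$stim_meta))
    utils::write.csv(tensor$stim_meta, file.path(path, "stim_meta.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read a response tensor container
#'
#' Accepts any schema version \code{1.x}; versions before 1.1 may lack a
#' baseline block.  Ground-truth simulator annotations are not serialized.
#'
#' @param path directory written by [write_tensor()].
#' @return A \code{response_tensor}.
#' @export
read_tensor <- function(path) {
  hp <- file.path(path, "header.json")
  if (!file.exists(hp)) stop("not a tensor container (no header.json): ", path)
  header <- jsonlite::fromJSON(readLines(hp))
  ver <- as.character(header$schema_version)
  if (!grepl("^1\\.", ver))
    stop("unsupported tensor schema version: ", ver)
  if (is.null(header$window_labels) || length(header$window_labels) < 1)
    stop("malformed container: missing window labels")
  d <- unlist(header$dims)
  rates <- array(as.numeric(readLines(file.path(path, "rates.txt"))),
                 dim = d,
                 dimnames = list(NULL, NULL, NULL, header$window_labels))
  if (length(rates) != prod(d)) stop("malformed container: rates length mismatch")
  baseline <- NULL
  bp <- file.path(path, "baseline.txt")
  if (file.exists(bp))
    baseline <- array(as.numeric(readLines(bp)), dim = d[1:3])
  site_meta <- utils::read.csv(file.path(path, "site_meta.csv"),
                               stringsAsFactors = FALSE)
  stimulus_ids <- readLines(file.path(path, "stimulus_ids.txt"))
  smp <- file.path(path, "stim_meta.csv")
  stim_meta <- if (file.exists(smp))
    utils::read.csv(smp, stringsAsFactors = FALSE) else NULL
  structure(list(rates = rates, baseline = baseline,
                 window_labels = header$window_labels,
                 site_meta = site_meta, stimulus_ids = stimulus_ids,
                 stim_meta = stim_meta, truth = NULL, config = NULL,
                 schema_version = ver),
            class = "response_tensor")
}
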