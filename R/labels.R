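#' Read an Audacity-style label track
#'
#' Parses a plain-text label track: one note per line,
#' \code{start<TAB>end<TAB>label}, times in seconds from the start of the
#' recording. Entries are returned sorted by start time.
#'
#' @param path Path to the label file.
#' @return A data frame with columns \code{start}, \code{end} (seconds)
#'   and \code{label} (character). Empty file gives zero rows.
#' @export
read_label_track <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("label track line without two TAB-separated times")
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(start) || anyNA(end)) stop("non-numeric time in label track")
  label <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", "")
  if (any(end <= start)) stop("label with end <= start")
  o <- order(start)
  d <- data.frame(start = start[o], end = end[o], label = label[o],
                  stringsAsFactors = FALSE)
  if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
    stop("overlapping label intervals")
  }
  d
}

#' Write an Audacity-style label track
#'
#' @param labels Data frame with columns \code{start}, \code{end},
#'   \code{label}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_label_track <- function(labels, path) {
  stopifnot(all(c("start", "end", "label") %in% names(labels)))
  lines <- sprintf("%.6f\t%.6f\t%s", labels$start, labels$end, labels$label)
  writeLines(lines, path)
  invisible(path)
}
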