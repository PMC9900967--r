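#' Write a trajectory as delimited text
#'
#' One or two columns (`x`, optionally `s`) written at full double
#' precision (`%.17g`), so a read/write round trip reproduces the numeric
#' values bit-exactly. Sampling metadata travels in `#`-prefixed header
#' lines.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_text <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt %.17g", traj$dt), con)
  writeLines(sprintf("# t0 %.17g", traj$t0), con)
  if (!is.null(traj$s)) {
    writeLines(sprintf("%.17g\t%.17g", traj$x, traj$s), con)
  } else {
    writeLines(sprintf("%.17g", traj$x), con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_text()]
#'
#' @param path input file path.
#' @return A [trajectory()].
#' @export
read_trajectory_text <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^# ", key, " "), "", m[1])) else default
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  x <- as.numeric(vapply(parts, `[`, character(1), 1))
  s <- if (length(parts[[1]]) > 1)
    as.numeric(vapply(parts, `[`, character(1), 2)) else NULL
  trajectory(x, dt = get("dt", 1), s = s, t0 = get("t0", 0))
}

#' Write/read one-column series (durations, slow coordinates)
#'
#' @param x numeric vector.
#' @param path file path.
#' @return `path` invisibly / the numeric vector.
#' @export
write_series_text <- function(x, path) {
  writeLines(sprintf("%.17g", as.numeric(x)), path)
  invisible(path)
}

#' @rdname write_series_text
#' @export
read_series_text <- function(path) {
  as.numeric(readLines(path))
}

#' Serialize an analysis object to JSON
#'
#' Drops function-valued fields (evaluator contracts) and writes the rest
#' with `jsonlite` at full precision.
#'
#' @param x a list-like object (tail fits, KM models, Markov models, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  strip <- function(v) {
    if (is.function(v)) return(NULL)
    if (is.list(v) && !is.data.frame(v)) {
      v <- lapply(v, strip)
      v[!vapply(v, is.null, logical(1))]
    } else v
  }
  jsonlite::write_json(strip(unclass_deep(x)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
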