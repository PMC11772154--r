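# Delimited-text I/O for weekly record tables (AmeriFlux-style headers plus
# an ISO week-start date) and flat key=value run configuration files.

#' Write a weekly record table as tab-delimited text
#'
#' @param df Weekly table (e.g. from [gen_bog_weekly()] or
#'   [derive_micromet()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weekly <- function(df, path) {
  if ("week_start" %in% names(df)) df$week_start <- as.character(df$week_start)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weekly record table written by [write_weekly()]
#'
#' @param path Input file path.
#' @return data.frame with `week_start` parsed as Date.
#' @export
read_weekly <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  if ("week_start" %in% names(df)) df$week_start <- as.Date(df$week_start)
  df
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; comma-separated
#' values become vectors; numeric-looking values are converted.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) parts <- nums
    else if (all(parts %in% c("TRUE", "FALSE", "true", "false")))
      parts <- toupper(parts) == "TRUE"
    out[[key]] <- parts
  }
  out
}

#' Write a flat key = value configuration file
#'
#' @param config Named list of scalars/vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
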