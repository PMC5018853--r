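# Plain-text interchange: tab-separated time series (site_id / time / freq),
# JSON run configurations, and a converter from allele-count tables.

#' Read frequency time series from a TSV file
#'
#' Expects a header `site_id<TAB>time<TAB>freq`; rows are grouped by site,
#' sorted by time and validated (frequencies in `[0, 1]`, no duplicated
#' `(site, time)` pairs).  Parse problems are reported with the offending row
#' numbers.
#'
#' @param path Path to the TSV file.
#' @return A named list of [wf_series()] objects.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.delim(path, colClasses = c("character", "numeric", "numeric")),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e)))
  if (!identical(names(df), c("site_id", "time", "freq")))
    stop("malformed header in '", path, "': expected site_id, time, freq; got ",
         paste(names(df), collapse = ", "))
  if (nrow(df) == 0L) stop("empty series file: ", path)
  bad <- which(!is.finite(df$freq) | df$freq < 0 | df$freq > 1)
  if (length(bad))
    stop("frequency outside [0, 1] at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad_t <- which(!is.finite(df$time) | df$time < 0)
  if (length(bad_t))
    stop("invalid time at data row(s) ", paste(utils::head(bad_t, 5L), collapse = ", "))
  dup <- which(duplicated(df[c("site_id", "time")]))
  if (length(dup))
    stop("duplicated (site_id, time) at data row(s) ",
         paste(utils::head(dup, 5L), collapse = ", "))
  out <- lapply(split(df, df$site_id), function(d) {
    d <- d[order(d$time), ]
    wf_series(d$time, d$freq, site_id = d$site_id[1])
  })
  out[order(names(out))]
}

#' Write frequency time series to a TSV file
#'
#' Deterministic output: rows ordered by site then time, frequencies printed
#' with 10 significant digits.  Round-trips exactly through [read_series()].
#'
#' @param series A `"wf_series"` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  if (inherits(series, "wf_series")) series <- list(series)
  rows <- lapply(series, function(s)
    data.frame(site_id = s$site_id, time = s$times,
               freq = sprintf("%.10g", s$freqs)))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), time = numeric(), freq = character())
  if (nrow(df)) df <- df[order(df$site_id, df$time), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("site_id\ttime\tfreq", con)
  if (nrow(df))
    writeLines(sprintf("%s\t%g\t%s", df$site_id, df$time, df$freq), con)
  invisible(path)
}

#' Convert an allele-count table to a frequency table
#'
#' Convenience converter from sequencing-style count data: a data frame with
#' columns `site_id`, `time`, `alt_count`, `depth` becomes the `site_id`,
#' `time`, `freq` layout used throughout, with `freq = alt_count / depth`.
#' Note the likelihood machinery treats these frequencies as exact; binomial
#' sampling noise from finite depth is not modelled.
#'
#' @param counts Data frame with columns `site_id`, `time`, `alt_count`,
#'   `depth`.
#' @return Data frame with columns `site_id`, `time`, `freq`.
#' @export
counts_to_freq <- function(counts) {
  need <- c("site_id", "time", "alt_count", "depth")
  if (!all(need %in% names(counts)))
    stop("'counts' needs columns: ", paste(need, collapse = ", "))
  if (any(counts$depth <= 0)) stop("'depth' must be positive")
  if (any(counts$alt_count < 0 | counts$alt_count > counts$depth))
    stop("'alt_count' must lie in [0, depth]")
  data.frame(site_id = counts$site_id, time = counts$time,
             freq = counts$alt_count / counts$depth)
}

#' Read / write a run configuration
#'
#' JSON serialization of the knobs of a simulation + inference run: model
#' parameters, initial frequency, span and sampling interval, site-set
#' composition, seeds, fit bounds and the density backend.  Round-trips
#' losslessly.
#'
#' @param path JSON file path.
#' @return For `read_run_config`, a named list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$params)) cfg$params <- do.call(wf_params, as.list(cfg$params))
  cfg
}

#' @rdname read_run_config
#' @param config Named list (may contain a [wf_params()] under `params`).
#' @export
write_run_config <- function(config, path) {
  if (inherits(config$params, "wf_params")) config$params <- unclass(config$params)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
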