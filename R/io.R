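# Delimited-text readers/writers for the package's table formats and the
# JSON run manifest. Comma-separated with a header row; numeric values are
# written with full (15 significant digit) precision so write-then-read
# round-trips are lossless at that precision.

.write_table <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 15, trim = TRUE, scientific = NA)
    else col
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a per-beat APD series as CSV
#'
#' Columns: `beat`, `apd_ms`, `upstroke_ms`, `flag` (`valid` or
#' `repolarization_failure`).
#'
#' @param x an [apd_series()].
#' @param path file path.
#' @return `read_apd_series` returns an [apd_series()];
#'   `write_apd_series` returns `path` invisibly.
#' @export
write_apd_series <- function(x, path) {
  stopifnot(inherits(x, "apd_series"))
  df <- data.frame(beat = seq_along(x$apd), apd_ms = x$apd,
                   upstroke_ms = x$upstroke_times,
                   flag = ifelse(x$valid, "valid", "repolarization_failure"))
  .write_table(df, path)
  invisible(path)
}

#' @rdname write_apd_series
#' @export
read_apd_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("beat", "apd_ms")
  if (!all(need %in% names(df))) {
    stop("APD series file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  apd_series(df$apd_ms,
             upstroke_times = df$upstroke_ms %||% rep(NA_real_, nrow(df)),
             valid = if (!is.null(df$flag)) df$flag == "valid" else NULL)
}

#' Write a simulation trace as CSV
#'
#' Columns: `time_ms`, `vm_mv`, `im_papf`, `cai_mm`, `casr_mm` (plus per-cell
#' columns for coupled runs), at the 0.5 ms recording resolution.
#'
#' @param trace data.frame from a `bvr_run` with `record_trace = TRUE`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  names(trace)[names(trace) == "time"] <- "time_ms"
  names(trace)[names(trace) == "vm"] <- "vm_mv"
  names(trace)[names(trace) == "im"] <- "im_papf"
  names(trace)[names(trace) == "cai"] <- "cai_mm"
  names(trace)[names(trace) == "casr"] <- "casr_mm"
  .write_table(trace, path)
  invisible(path)
}

#' Write a BVR summary as JSON
#'
#' @param summary list from [bvr_summary()].
#' @param path file path.
#' @export
write_bvr_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration hash, master seed, package version and output
#' files of a run, so that every output is traceable.
#'
#' @param config the configuration list used.
#' @param seed master seed.
#' @param outputs character vector of output file paths.
#' @param path manifest path (JSON).
#' @export
write_manifest <- function(config, seed, outputs, path) {
  cfg_str <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "bvrsim",
    version = as.character(utils::packageVersion("bvrsim")),
    config_hash = sprintf("%08x", .simple_hash(cfg_str)),
    seed = seed,
    outputs = outputs,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# djb2-style rolling hash over the serialized configuration (31-bit)
.simple_hash <- function(s) {
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Read a cell/protocol configuration overlay from JSON
#'
#' The file may contain any subset of the configuration tree of
#' [default_cell_config()] plus optional `condition`, `domains` and
#' `protocol` blocks; values present override the defaults.
#'
#' @param path JSON file path.
#' @return list with `config`, `condition`, `domains`, `protocol`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- default_cell_config()
  if (!is.null(raw$cell)) config <- modifyList(config, raw$cell)
  condition <- if (!is.null(raw$condition)) {
    do.call(condition_spec, raw$condition)
  } else condition_spec()
  domains <- if (!is.null(raw$domains)) {
    do.call(domain_config, raw$domains)
  } else domain_config()
  list(config = config, condition = condition, domains = domains,
       protocol = raw$protocol)
}
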