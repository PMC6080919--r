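#' Read and write trajectory tables
#'
#' Comma-separated, '.' decimal, UTF-8, mandatory header with columns
#' `oocyte, chromosome, t_s, x_um, y_um, z_um`. Reading sorts rows into the
#' canonical `(oocyte, chromosome, t_s)` order, validates per-track time
#' monotonicity and rejects missing columns or non-finite coordinates with
#' row numbers; writing round-trips at full float precision.
#'
#' @param path File path.
#' @return `read_trajectories()` returns the trajectory tibble.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("oocyte", "chromosome", "t_s", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[need]) |
                 !is.finite(df$x_um) | !is.finite(df$y_um) |
                 !is.finite(df$z_um) | !is.finite(df$t_s))
  if (length(bad)) {
    stop("non-finite or missing values at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  # reject tracks whose recorded time runs backward, and duplicate frames
  rev_check <- df |>
    dplyr::group_by(.data$oocyte, .data$chromosome) |>
    dplyr::summarise(
      reversed = dplyr::n() > 1 && all(diff(.data$t_s) < 0),
      dup = anyDuplicated(.data$t_s) > 0, .groups = "drop") |>
    dplyr::filter(.data$reversed | .data$dup)
  if (nrow(rev_check)) {
    stop(sprintf("invalid time course in track oocyte %s chromosome %s",
                 rev_check$oocyte[1], rev_check$chromosome[1]),
         call. = FALSE)
  }
  dplyr::arrange(df, .data$oocyte, .data$chromosome, .data$t_s)
}

#' @rdname read_trajectories
#' @param trajectories Trajectory tibble; an `oocyte` column is added
#'   (value 1) if absent.
#' @export
write_trajectories <- function(trajectories, path) {
  check_trajectory_cols(trajectories)
  if (!"oocyte" %in% names(trajectories)) {
    trajectories <- dplyr::mutate(trajectories, oocyte = 1L, .before = 1)
  }
  cols <- c("oocyte", "chromosome", "t_s", "x_um", "y_um", "z_um")
  df <- dplyr::arrange(trajectories[cols], .data$oocyte,
                       .data$chromosome, .data$t_s)
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_full <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) format(col, digits = 17, trim = TRUE,
                               scientific = FALSE) else col
  }))
}

#' Read and write flat key = value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers where possible, `TRUE`/`FALSE` as logicals, otherwise kept as
#' strings. The gate schedule is encoded as `gate_times` / `gate_fractions`
#' comma-separated lists.
#'
#' @param path File path.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) {
      num
    } else if (all(parts %in% c("TRUE", "FALSE"))) {
      as.logical(parts)
    } else {
      parts
    }
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.double(v)) v <- format(v, digits = 17, trim = TRUE)
    sprintf("%s = %s", k, paste(v, collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize simulation parameters to/from a config list
#'
#' @param params A [sim_params()].
#' @return `params_to_config()` returns a flat named list (gate encoded as
#'   `gate_times`/`gate_fractions`); `config_to_params()` rebuilds a
#'   validated `sim_params` from such a list, using defaults for absent
#'   keys.
#' @export
params_to_config <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  cfg <- unclass(params)
  cfg$gate_times <- params$gate$time
  cfg$gate_fractions <- params$gate$fraction
  cfg$gate <- NULL
  cfg
}

#' @rdname params_to_config
#' @param config Named list as produced by [params_to_config()] or
#'   [read_config()].
#' @export
config_to_params <- function(config) {
  gate <- if (!is.null(config$gate_times)) {
    gate_schedule(data.frame(time = config$gate_times,
                             fraction = config$gate_fractions))
  } else {
    gate_schedule()
  }
  config$gate_times <- NULL
  config$gate_fractions <- NULL
  known <- names(formals(sim_params))
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_params, c(config, list(gate = gate)))
}

#' Write a run manifest
#'
#' Records the resolved configuration, seed, package version, input/output
#' file checksums and a timestamp, sufficient to reproduce a run.
#'
#' @param path Output path for the JSON manifest.
#' @param config Named list of resolved configuration values.
#' @param seed Integer seed used.
#' @param files Character vector of input/output file paths to checksum.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, files = character()) {
  files <- files[file.exists(files)]
  manifest <- list(
    tool = "congressim",
    version = as.character(utils::packageVersion("congressim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read/write 4D image stacks as multi-page TIFF
#'
#' Pages are z-slices ordered frame-major (frame 1 z 1..nz, frame 2 ...).
#' Requires the `tiff` package.
#'
#' @param stack 4D numeric array (x, y, z, frame); values are scaled to
#'   the 16-bit range on write using `max_value`.
#' @param path File path.
#' @param max_value Intensity mapped to the TIFF white point (default the
#'   stack maximum).
#' @return `read_stack()` returns a 4D array scaled back by `max_value`.
#' @export
write_stack <- function(stack, path, max_value = max(stack)) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF output", call. = FALSE)
  }
  d <- dim(stack)
  pages <- lapply(seq_len(d[3] * d[4]), function(i) {
    f <- (i - 1) %/% d[3] + 1
    z <- (i - 1) %% d[3] + 1
    t(stack[, , z, f]) / max_value
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @param nz Number of z-slices per frame.
#' @export
read_stack <- function(path, nz, max_value = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF input", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% nz != 0) {
    stop("page count is not a multiple of `nz`", call. = FALSE)
  }
  nf <- length(pages) / nz
  d <- dim(pages[[1]])
  out <- array(0, c(d[2], d[1], nz, nf))
  for (i in seq_along(pages)) {
    f <- (i - 1) %/% nz + 1
    z <- (i - 1) %% nz + 1
    out[, , z, f] <- t(pages[[i]])
  }
  out * max_value
}
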