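#' Write a curve to CSV
#'
#' One unambiguous dialect: comma-separated, `.` decimal, UTF-8, LF line
#' endings, header always present, numbers rendered with 9 significant
#' digits. A read of the written file reproduces the samples to 1e-9
#' relative.
#'
#' @param curve A `force_extension_curve` (or plain data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  cols <- lapply(df, function(col) {
    if (is.double(col)) formatC(col, digits = 9, format = "g") else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df) > 0) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a curve CSV written by [write_curve_csv()]
#'
#' @param path Input file path.
#' @param scale Curve scale to stamp on the result (default `"reference"`).
#' @return A `force_extension_curve`.
#' @export
read_curve_csv <- function(path, scale = "reference") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  new_force_extension_curve(df, scale = scale, metadata = list(source = path))
}

#' Read a user-supplied two-column reference curve
#'
#' Reads a digitized experimental curve as a two-column numeric CSV
#' (independent variable, force), with or without a header row. Rows that
#' break strict monotonicity of the independent variable are dropped with a
#' warning reporting the count; non-numeric rows are an error listing the
#' offending line numbers. No reference data ships with the package.
#'
#' @param path Input file path.
#' @return A `force_extension_curve` of scale `"reference"` with columns `x`
#'   and `force`.
#' @export
read_reference_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0) abort(sprintf("reference file is empty: %s", path))
  fields <- strsplit(raw, ",", fixed = TRUE)
  header_offset <- 0L
  first <- suppressWarnings(as.numeric(fields[[1]]))
  if (any(is.na(first))) {      # header row
    header_offset <- 1L
    fields <- fields[-1]
    if (length(fields) == 0) abort(sprintf("reference file has no data rows: %s", path))
  }
  bad_ncol <- which(lengths(fields) < 2)
  vals <- suppressWarnings(lapply(fields, function(f) as.numeric(f[1:2])))
  bad <- sort(unique(c(bad_ncol,
                       which(vapply(vals, function(v) any(is.na(v)), logical(1))))))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or malformed row(s) in %s at line(s): %s",
                  path, paste(bad + header_offset, collapse = ", ")))
  }
  m <- do.call(rbind, vals)
  keep <- rep(TRUE, nrow(m))
  x_last <- -Inf
  for (i in seq_len(nrow(m))) {
    if (m[i, 1] > x_last) x_last <- m[i, 1] else keep[i] <- FALSE
  }
  if (any(!keep)) {
    warn(sprintf("dropped %d row(s) violating strict monotonicity of x in %s",
                 sum(!keep), path))
  }
  new_force_extension_curve(
    tibble(x = m[keep, 1], force = m[keep, 2]),
    scale = "reference", metadata = list(source = path, dropped = sum(!keep))
  )
}

#' RMS deviation between a model curve and a reference curve
#'
#' Root-mean-square of the force differences at the reference abscissae, with
#' the model curve linearly interpolated there. Not symmetric in its
#' arguments: the reference provides the evaluation points. Reference points
#' outside the model's range are excluded; if none overlap, an error is
#' raised.
#'
#' @param model A `force_extension_curve` (any scale).
#' @param ref A reference curve, e.g. from [read_reference_csv()].
#' @return A single non-negative number in the model's force unit.
#' @export
rms_deviation <- function(model, ref) {
  mn <- curve_xy_names(model)
  rn <- curve_xy_names(ref)
  mx <- model[[mn[1]]]; my <- model[[mn[2]]]
  rx <- ref[[rn[1]]]; ry <- ref[[rn[2]]]
  inside <- rx >= min(mx) & rx <= max(mx)
  if (!any(inside)) {
    abort("model and reference curves have no overlapping range")
  }
  pred <- approx(mx, my, xout = rx[inside], ties = "ordered")$y
  sqrt(mean((pred - ry[inside])^2))
}

#' Write a machine-readable run record
#'
#' JSON sidecar describing a run completely enough to reproduce it: command,
#' resolved configuration, derived counts, package version, timestamp and a
#' convergence summary. Written next to each CLI output.
#'
#' @param path Output JSON path.
#' @param command Command name and flags (character).
#' @param config Resolved configuration (list as from [read_fibrin_config()]).
#' @param derived Named list of derived quantities (counts, break step, ...).
#' @return `path`, invisibly.
#' @export
write_run_record <- function(path, command, config, derived = list()) {
  rec <- list(
    command = command,
    package_version = as.character(utils::packageVersion("fibrinet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = lapply(config, unclass),
    derived = derived
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
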