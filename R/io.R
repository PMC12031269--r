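# Delimited-text formats with '#'-prefixed metadata headers. Chosen over
# binary containers because instrument exports are tabular and plain text
# diffs cleanly in version control.

parse_metadata_lines <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      meta[[key]] <- val
    }
  }
  meta
}

detect_delim <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

# read a delimited table with '#' metadata; errors carry file line numbers
read_table_file <- function(path, required_cols) {
  if (!file.exists(path)) {
    ncis_abort(sprintf("File not found: %s", path), "ncis_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_line_numbers <- which(is_data)
  if (length(data_line_numbers) == 0) {
    ncis_abort(sprintf("%s: no table found (comment/empty lines only).", path),
               "ncis_parse_error")
  }
  delim <- detect_delim(lines[data_line_numbers[1]])
  tbl <- suppressWarnings(readr::read_delim(
    I(paste(lines[is_data], collapse = "\n")),
    delim = delim, show_col_types = FALSE, progress = FALSE
  ))
  missing_cols <- setdiff(required_cols, names(tbl))
  if (length(missing_cols) > 0) {
    ncis_abort(sprintf("%s: missing column(s) %s (line %d).",
                       path, paste(sprintf("`%s`", missing_cols), collapse = ", "),
                       data_line_numbers[1]),
               "ncis_parse_error")
  }
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    # problems() rows are 1-based over data rows incl. header
    file_line <- data_line_numbers[pmin(probs$row[1], length(data_line_numbers))]
    ncis_abort(sprintf("%s: could not parse value in column %s (line %d).",
                       path, probs$col[1], file_line),
               "ncis_parse_error")
  }
  for (col in required_cols) {
    bad <- which(!is.finite(tbl[[col]]) | !is.numeric(tbl[[col]]))
    if (!is.numeric(tbl[[col]]) || length(bad) > 0) {
      row <- if (length(bad) > 0) bad[1] else 1L
      file_line <- data_line_numbers[row + 1L]  # +1 for header line
      ncis_abort(sprintf("%s: non-numeric value in column `%s` (line %d).",
                         path, col, file_line),
                 "ncis_parse_error")
    }
  }
  if (nrow(tbl) == 0) {
    ncis_abort(sprintf("%s: table has a header but no records.", path),
               "ncis_parse_error")
  }
  list(table = tbl, meta = parse_metadata_lines(lines))
}

#' Read and write conductivity-sweep files
#'
#' Sweep files are delimited text (comma or tab) with header columns
#' `freq_hz`, `kappa_s_per_m`, `re_dz_ohm`, `neg_im_dz_ohm`, preceded by
#' optional `#`-prefixed metadata lines (`baseline_label`, `eps_r`,
#' `kappa_b`). Round trips are lossless to full double precision.
#'
#' @param path File path.
#' @param sweep A sweep tibble (see [gen_sweep()]).
#' @return `read_sweep()` returns a sweep tibble with metadata attributes;
#'   `write_sweep()` returns `path` invisibly.
#' @examples
#' p <- circuit_params(6e-12, kappa_b = 5.5e-6)
#' sw <- gen_sweep(p, 1e4, c(1e-5, 1e-4))
#' f <- tempfile(fileext = ".csv")
#' write_sweep(sw, f)
#' read_sweep(f)
#' @export
read_sweep <- function(path) {
  parsed <- read_table_file(
    path, c("freq_hz", "kappa_s_per_m", "re_dz_ohm", "neg_im_dz_ohm"))
  tbl <- parsed$table
  if (anyDuplicated(tbl[c("freq_hz", "kappa_s_per_m")]) > 0) {
    dup <- which(duplicated(tbl[c("freq_hz", "kappa_s_per_m")]))[1]
    ncis_abort(sprintf("%s: duplicate (freq, kappa) pair at data row %d.",
                       path, dup),
               "ncis_parse_error")
  }
  sweep <- validate_sweep(tbl)
  meta <- parsed$meta
  attr(sweep, "baseline_label") <- meta$baseline_label %||% NA_character_
  if (!is.null(meta$eps_r)) attr(sweep, "eps_r") <- as.numeric(meta$eps_r)
  if (!is.null(meta$kappa_b)) attr(sweep, "kappa_b") <- as.numeric(meta$kappa_b)
  sweep
}

#' @rdname read_sweep
#' @export
write_sweep <- function(sweep, path) {
  sweep <- validate_sweep(sweep)
  header <- c(
    sprintf("# baseline_label = %s", attr(sweep, "baseline_label") %||% "unknown"),
    if (!is.null(attr(sweep, "eps_r"))) sprintf("# eps_r = %.17g", attr(sweep, "eps_r")),
    if (!is.null(attr(sweep, "kappa_b"))) sprintf("# kappa_b = %.17g", attr(sweep, "kappa_b"))
  )
  writeLines(header, path)
  readr::write_csv(as_tibble(sweep), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write growth-curve files
#'
#' Curve files are delimited text with columns `time_h` and `value`, preceded
#' by optional `#` metadata (`channel`, `units`, `invert`).
#'
#' @param path File path.
#' @param curve A tibble with columns `time_h`, `value`.
#' @param channel,units,invert Metadata written to the header.
#' @return `read_curve()` returns a curve tibble with attributes `channel`,
#'   `units` and `invert`; `write_curve()` returns `path` invisibly.
#' @export
read_curve <- function(path) {
  parsed <- read_table_file(path, c("time_h", "value"))
  curve <- as_tibble(parsed$table[c("time_h", "value")])
  meta <- parsed$meta
  attr(curve, "channel") <- meta$channel %||% NA_character_
  attr(curve, "units") <- meta$units %||% NA_character_
  attr(curve, "invert") <- identical(tolower(meta$invert %||% "false"), "true")
  curve
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path, channel = NULL, units = NULL,
                        invert = FALSE) {
  if (!is.data.frame(curve) || !all(c("time_h", "value") %in% names(curve))) {
    ncis_abort("`curve` needs columns `time_h` and `value`.",
               "ncis_invalid_input")
  }
  header <- c(
    sprintf("# channel = %s", channel %||% attr(curve, "channel") %||% "unknown"),
    sprintf("# units = %s", units %||% attr(curve, "units") %||% "unknown"),
    sprintf("# invert = %s", tolower(as.character(invert)))
  )
  writeLines(header, path)
  readr::write_csv(as_tibble(curve)[c("time_h", "value")], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

known_manifest_keys <- c("tsample_h", "reference")
channel_manifest_fields <- c("file", "units", "invert", "role")

#' Read and write experiment bundles
#'
#' An experiment bundle is a directory of per-channel curve files plus a
#' flat key-value manifest (`key = value` per line):
#' `tsample_h`, `reference`, and per channel
#' `channel.<label>.file`, `channel.<label>.units`, `channel.<label>.invert`,
#' `channel.<label>.role`. Unknown keys produce a warning, never a failure;
#' missing channel files and duplicate channel labels are errors.
#'
#' @param manifest_path Path to the manifest file.
#' @param exp An [ncis_experiment()].
#' @param dir Output directory (created if needed).
#' @return `read_experiment()` returns an [ncis_experiment()];
#'   `write_experiment()` returns the manifest path invisibly.
#' @examples
#' exp <- ncis_scenario("s_epidermidis_bottle")
#' d <- tempfile()
#' write_experiment(exp, d)
#' read_experiment(file.path(d, "manifest.txt"))
#' @export
read_experiment <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    ncis_abort(sprintf("Manifest not found: %s", manifest_path),
               "ncis_parse_error")
  }
  lines <- readLines(manifest_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  keys <- character(0)
  vals <- character(0)
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE)) {
      ncis_abort(sprintf("%s: line %d is not `key = value`.", manifest_path, i),
                 "ncis_parse_error")
    }
    keys[i] <- trimws(sub("=.*$", "", lines[i]))
    vals[i] <- trimws(sub("^[^=]*=", "", lines[i]))
  }
  if (anyDuplicated(keys) > 0) {
    ncis_abort(sprintf("%s: duplicate key `%s`.", manifest_path,
                       keys[duplicated(keys)][1]),
               "ncis_parse_error")
  }
  kv <- setNames(as.list(vals), keys)

  ch_keys <- grep("^channel\\.", keys, value = TRUE)
  parts <- strsplit(ch_keys, ".", fixed = TRUE)
  labels <- unique(vapply(parts, function(p) paste(p[-c(1, length(p))], collapse = "."),
                          character(1)))
  if (length(labels) == 0) {
    ncis_abort(sprintf("%s: manifest defines no channels.", manifest_path),
               "ncis_parse_error")
  }
  plain <- keys[!grepl("^channel\\.", keys) & !grepl("^meta\\.", keys)]
  unknown <- setdiff(plain, known_manifest_keys)
  fields <- vapply(parts, function(p) p[length(p)], character(1))
  unknown <- c(unknown, ch_keys[!fields %in% channel_manifest_fields])
  if (length(unknown) > 0) {
    warn(sprintf("%s: ignoring unknown manifest key(s): %s.", manifest_path,
                 paste(unknown, collapse = ", ")))
  }

  base_dir <- dirname(manifest_path)
  curves <- list()
  info_rows <- list()
  for (lab in labels) {
    get <- function(field, default = NA_character_) {
      kv[[sprintf("channel.%s.%s", lab, field)]] %||% default
    }
    file <- get("file")
    if (is.na(file)) {
      ncis_abort(sprintf("%s: channel `%s` has no file entry.", manifest_path, lab),
                 "ncis_parse_error")
    }
    fpath <- file.path(base_dir, file)
    if (!file.exists(fpath)) {
      ncis_abort(sprintf("%s: channel `%s` references missing file %s.",
                         manifest_path, lab, fpath),
                 "ncis_parse_error")
    }
    curves[[lab]] <- read_curve(fpath)
    info_rows[[lab]] <- tibble(
      channel = lab,
      units = get("units"),
      invert = identical(tolower(get("invert", "false")), "true"),
      role = get("role", "impedance")
    )
  }

  ncis_experiment(
    curves,
    channel_info = bind_rows(info_rows),
    tsample_h = as.numeric(kv$tsample_h %||% "0.5"),
    reference = kv$reference %||% "od_600",
    metadata = setNames(kv[grepl("^meta\\.", names(kv))],
                        sub("^meta\\.", "", names(kv)[grepl("^meta\\.", names(kv))]))
  )
}

#' @rdname read_experiment
#' @export
write_experiment <- function(exp, dir) {
  if (!inherits(exp, "ncis_experiment")) {
    ncis_abort("`exp` must be an ncis_experiment.", "ncis_invalid_input")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lines <- c(
    sprintf("tsample_h = %.17g", exp$tsample_h),
    sprintf("reference = %s", exp$reference)
  )
  if (length(exp$metadata) > 0 && !is.null(names(exp$metadata))) {
    lines <- c(lines, sprintf("meta.%s = %s", names(exp$metadata),
                              vapply(exp$metadata, as.character, character(1))))
  }
  for (ch in names(exp$curves)) {
    info <- exp$channel_info[exp$channel_info$channel == ch, ]
    fname <- paste0(gsub("[^A-Za-z0-9_.-]", "_", ch), ".csv")
    write_curve(exp$curves[[ch]], file.path(dir, fname), channel = ch,
                units = if (is.na(info$units[1])) "unknown" else info$units[1],
                invert = isTRUE(info$invert[1]))
    lines <- c(lines,
               sprintf("channel.%s.file = %s", ch, fname),
               sprintf("channel.%s.units = %s", ch,
                       if (is.na(info$units[1])) "unknown" else info$units[1]),
               sprintf("channel.%s.invert = %s", ch, tolower(isTRUE(info$invert[1]))),
               sprintf("channel.%s.role = %s", ch, info$role[1]))
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(lines, manifest)
  invisible(manifest)
}
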