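#' Read a columnar motion time-series file
#'
#' Reads the self-describing columnar text dialect used for motion data
#' (.sto/.mot style): a header with the table name, `nRows=`, `nColumns=`
#' and an `endheader` sentinel, a tab-separated column-label row whose
#' first column is time in seconds, then the data matrix. Angles are stored
#' in degrees in files; any unit conversion happens in the functions that
#' consume the tables.
#'
#' @param path file path.
#' @return a tibble (first column `time`), with attribute `name`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (length(end) != 1L) {
    abort(sprintf("%s: malformed header: expected exactly one 'endheader' line",
                  path))
  }
  header <- lines[seq_len(end - 1L)]
  get_num <- function(key) {
    hit <- grep(paste0("^", key, "="), header, value = TRUE)
    if (length(hit) != 1L) {
      abort(sprintf("%s: header line '%s=' missing or duplicated", path, key))
    }
    as.integer(sub(paste0("^", key, "="), "", hit))
  }
  n_rows <- get_num("nRows")
  n_cols <- get_num("nColumns")
  name <- header[1L]
  labels <- strsplit(lines[end + 1L], "\t", fixed = TRUE)[[1L]]
  if (length(labels) != n_cols) {
    abort(sprintf("%s: line %d: %d column labels but header declares nColumns=%d",
                  path, end + 1L, length(labels), n_cols))
  }
  body <- lines[(end + 2L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_rows) {
    abort(sprintf("%s: %d data rows but header declares nRows=%d",
                  path, length(body), n_rows))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  ncp <- lengths(parts)
  if (any(ncp != n_cols)) {
    bad <- which(ncp != n_cols)[1L]
    abort(sprintf("%s: data row %d has %d fields, expected %d",
                  path, bad, ncp[bad], n_cols))
  }
  mat <- matrix(as.numeric(unlist(parts)), nrow = n_rows, ncol = n_cols,
                byrow = TRUE)
  if (anyNA(mat)) abort(sprintf("%s: non-numeric data", path))
  if (any(diff(mat[, 1L]) <= 0)) {
    bad <- which(diff(mat[, 1L]) <= 0)[1L] + 1L
    abort(sprintf("%s: time not strictly increasing at data row %d", path, bad))
  }
  out <- as_tibble(as.data.frame(mat))
  names(out) <- labels
  attr(out, "name") <- name
  out
}

#' Write a columnar motion time-series file
#'
#' Counterpart of [read_timeseries()]. Values are written with 15
#' significant digits so a write-read round trip is lossless at double
#' precision for practical purposes.
#'
#' @param table data frame whose first column is a strictly increasing time
#'   vector (s).
#' @param path output file path.
#' @param name table name written on the first header line.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(table, path, name = "timeseries") {
  stopifnot(is.data.frame(table), ncol(table) >= 2L)
  if (any(diff(table[[1L]]) <= 0)) {
    abort("first column must be strictly increasing time")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(table)),
               sprintf("nColumns=%d", ncol(table)),
               "endheader",
               paste(names(table), collapse = "\t")), con)
  body <- apply(vapply(table, function(col) sprintf("%.15g", col),
                       character(nrow(table))),
                1L, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read / write a configuration file
#'
#' Key-value configuration in YAML markup.
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config a named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# write a run manifest (config echo + hash, seed, versions) next to outputs
write_manifest <- function(out_dir, config, seed) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package = "reflexgait",
    package_version = tryCatch(
      as.character(utils::packageVersion("reflexgait")),
      error = function(e) "dev"),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
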