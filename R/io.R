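# Readers/writers shared by all modules: fixed-precision CSV, flat
# key-value configs, result bundles and run manifests.

fmt_num <- function(x) trimws(formatC(x, digits = 12, format = "g"))

write_num_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an RF waveform as CSV
#'
#' Columns `time_s`, `re`, `im` (nutation rate in rad/s) with the
#' carrier offset and label carried in a header comment line.
#'
#' @param w an [rf_waveform].
#' @param path file path.
#' @return `path` invisibly (writer); an [rf_waveform] (reader).
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "rf_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rf_waveform dt=%s carrier_offset_hz=%s label=%s",
                     fmt_num(w$dt), fmt_num(w$carrier_offset_hz), w$label), con)
  df <- data.frame(time_s = fmt_num(waveform_times(w)),
                   re = fmt_num(Re(w$samples)), im = fmt_num(Im(w$samples)))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]*", hdr))[[1]]
  get <- function(key) sub(paste0(key, "="), "",
                           kv[startsWith(kv, paste0(key, "="))])
  df <- utils::read.csv(path, skip = 1)
  rf_waveform(complex(real = df$re, imaginary = df$im),
              dt = as.numeric(get("dt")),
              carrier_offset_hz = as.numeric(get("carrier_offset_hz")),
              label = get("label"))
}

#' Write / read a spectrum as CSV
#'
#' Columns `ppm`, `re`, `im`.
#' @param spec an [mrs_spectrum].
#' @param path file path.
#' @return `path` invisibly (writer); an [mrs_spectrum] (reader).
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  write_num_csv(data.frame(ppm = spec$ppm, re = Re(spec$intensity),
                           im = Im(spec$intensity)), path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  mrs_spectrum(df$ppm, complex(real = df$re, imaginary = df$im))
}

#' Flat key-value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' parsed as numeric vectors where possible (comma-separated), else
#' kept as strings. Unknown keys are the caller's to reject.
#'
#' @param path file path.
#' @param config named list (writer).
#' @return named list (reader); `path` invisibly (writer).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop(sprintf("malformed line: '%s'", ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    out[[key]] <- if (!any(is.na(num))) num else val
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    v <- if (is.numeric(v)) paste(fmt_num(v), collapse = ",") else as.character(v)
    sprintf("%s = %s", k, v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Save an edited result bundle
#'
#' Writes the full/partial/difference spectra as CSV files plus a JSON
#' manifest, and the complete object as an RDS container.
#'
#' @param result an `edited_result`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @param seed seed recorded in the manifest.
#' @return the manifest list, invisibly.
#' @export
save_edited_result <- function(result, dir, stem = "edited", seed = NA) {
  stopifnot(inherits(result, "edited_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (part in c("full", "partial", "difference"))
    write_spectrum_csv(result[[part]],
                       file.path(dir, sprintf("%s_%s.csv", stem, part)))
  saveRDS(result, file.path(dir, paste0(stem, ".rds")))
  write_manifest(file.path(dir, paste0(stem, "_manifest.json")),
                 list(scheme = result$scheme$name,
                      te_s = result$scheme$te_s,
                      system = result$system_name, seed = seed))
}

#' Write a run manifest
#'
#' JSON manifest with the package version, timestamp-free config echo
#' and seed, written beside every CLI output.
#'
#' @param path output path.
#' @param config named list echoed into the manifest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list()) {
  man <- c(list(package = "slowedit",
                version = as.character(utils::packageVersion("slowedit"))),
           config)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
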