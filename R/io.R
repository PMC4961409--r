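#' Read an abundance table into time series
#'
#' Two layouts are supported. \code{"tidy"}: one row per observation with
#' columns \code{host_id}, \code{species}, \code{time_hr}, \code{abundance}.
#' \code{"wide"}: a spreadsheet-style sheet with a \code{time_hr} column and
#' one column per host (optionally \code{host.species} headers), which is
#' reshaped to tidy form; missing cells are tolerated. In either layout, rows
#' with non-numeric or missing abundance are skipped and their count is
#' reported via a message.
#'
#' @param path CSV (or TSV; the separator is sniffed from the header line).
#' @param layout "tidy" or "wide".
#' @return a list of [abundance_series()], one per host-by-species.
#' @export
read_abundance_table <- function(path, layout = c("tidy", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("no data rows in ", path)

  if (layout == "tidy") {
    need <- c("host_id", "species", "time_hr", "abundance")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
    }
  } else {
    if (!"time_hr" %in% names(df)) {
      stop("missing mandatory column(s): time_hr")
    }
    hosts <- setdiff(names(df), "time_hr")
    if (!length(hosts)) stop("wide layout needs at least one host column")
    long <- do.call(rbind, lapply(hosts, function(h) {
      parts <- strsplit(h, ".", fixed = TRUE)[[1]]
      data.frame(host_id = parts[1],
                 species = if (length(parts) > 1) parts[2] else "",
                 time_hr = df$time_hr, abundance = df[[h]],
                 stringsAsFactors = FALSE)
    }))
    df <- long
  }

  ab <- suppressWarnings(as.numeric(df$abundance))
  tm <- suppressWarnings(as.numeric(df$time_hr))
  bad <- !is.finite(ab) | !is.finite(tm)
  if (any(bad)) {
    message("skipped ", sum(bad), " row(s) with non-numeric time or abundance")
  }
  df <- df[!bad, , drop = FALSE]
  df$abundance <- ab[!bad]
  df$time_hr <- tm[!bad]
  if (nrow(df) == 0) stop("no usable rows in ", path)

  key <- interaction(df$host_id, df$species, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_hr), , drop = FALSE]
    abundance_series(g$host_id[1], g$species[1], g$time_hr, g$abundance)
  })
}

#' Write abundance series to a tidy CSV
#'
#' @param series_list list of [abundance_series()] (or a single one).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_abundance_table <- function(series_list, path) {
  if (inherits(series_list, "abundance_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected or simulated collapse events to CSV
#'
#' Columns: host_id, time_hr, n_before, n_after, f.
#'
#' @param events a \code{collapse_events} data frame (or a trajectory's
#'   \code{events} component).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(host_id = events$host_id, time_hr = events$time,
                    n_before = events$n_before, n_after = events$n_after,
                    f = events$f, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an endpoint (plating) table
#'
#' Expects columns \code{host_id}, \code{condition}, \code{abundance_cfu};
#' one ensemble per condition is returned.
#'
#' @param path CSV path.
#' @param t_final hours since inoculation/challenge, attached to each
#'   ensemble.
#' @param lod,loq censoring limits attached to each ensemble.
#' @return named list of [endpoint_ensemble()], one per condition.
#' @export
read_endpoint_table <- function(path, t_final = NA_real_, lod = 5, loq = 100) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("host_id", "condition", "abundance_cfu")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  lapply(split(df, df$condition), function(g) {
    endpoint_ensemble(g$abundance_cfu, host_ids = g$host_id,
                      condition = g$condition[1], t_final = t_final,
                      lod = lod, loq = loq)
  })
}

#' @rdname read_endpoint_table
#' @param ensemble an [endpoint_ensemble()] to write.
#' @export
write_endpoint_table <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "endpoint_ensemble"))
  df <- data.frame(host_id = ensemble$host_ids,
                   condition = ensemble$condition,
                   abundance_cfu = ensemble$abundances,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.param_keys <- c("r", "K", "sigma_logK", "p_c", "mu_logf", "sigma_logf",
                 "extinction_threshold")

#' Read / write model parameters as a flat key-value config
#'
#' TOML-style \code{key = value} lines with the keys \code{r}, \code{K},
#' \code{sigma_logK}, \code{p_c}, \code{mu_logf}, \code{sigma_logf},
#' \code{extinction_threshold}. Parsing is strict: unknown keys are rejected,
#' comments (\code{#}) and blank lines are ignored.
#'
#' @param path config file path.
#' @return [read_collapse_params()]: a [collapse_params()] object.
#' @export
read_collapse_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("unparseable config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 3)))
  unknown <- setdiff(keys, .param_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(keys)) stop("duplicated config key(s)")
  if (any(!is.finite(vals))) stop("non-numeric config value(s)")
  args <- as.list(vals)
  names(args) <- keys
  do.call(collapse_params, args)
}

#' @rdname read_collapse_params
#' @param params a [collapse_params()] object to write.
#' @export
write_collapse_params <- function(params, path) {
  stopifnot(inherits(params, "collapse_params"))
  lines <- vapply(.param_keys, function(k) {
    sprintf("%s = %.17g", k, params[[k]])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a collapse-model fit
#'
#' Writes the fitted coefficients, observed statistics, uncertainty region
#' and settings as JSON, and the full objective surface as CSV next to it
#' (same stem, \code{_surface.csv} suffix).
#'
#' @param fit a \code{collapse_fit}.
#' @param path output JSON path.
#' @return the JSON path, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "collapse_fit"))
  payload <- list(
    log10_K = fit$coefficients[["log10_K"]],
    z = fit$coefficients[["z"]],
    observed = fit$observed,
    uncertainty = fit$uncertainty,
    settings = fit$settings[c("r", "n0", "p_c", "extinction_threshold",
                              "n_sim", "seed", "t_final", "lod", "loq",
                              "weights", "n_hosts")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  surface_path <- sub("\\.json$", "", path)
  utils::write.csv(fit$surface, paste0(surface_path, "_surface.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable provenance record
#'
#' Every analysis output can be re-derived from this record: package version,
#' timestamp, seed, the full settings list, and a content hash (FNV-1a over
#' the serialized settings) so records can be compared cheaply.
#'
#' @param path output JSON path.
#' @param seed the seed the run used.
#' @param settings named list of every threshold and parameter of the run.
#' @return the settings hash, invisibly.
#' @export
write_provenance <- function(path, seed, settings = list()) {
  serialized <- jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA)
  record <- list(
    package = "popcollapse",
    version = as.character(utils::packageVersion("popcollapse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    settings = settings,
    settings_hash = .fnv1a(as.character(serialized)))
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA)
  invisible(record$settings_hash)
}

# 32-bit FNV-1a over a string, returned as 8 hex digits; arithmetic is kept
# below 2^53 so plain doubles stay exact
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%08x", h)
}
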