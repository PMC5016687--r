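#' Read and write titration CSV files
#'
#' The titration dialect is a plain CSV with columns
#' `titrant_monomer_M, delta_r`, preceded by `#`-prefixed header
#' metadata lines of the form `# key=value`; `probe_total_M` is
#' mandatory, `replicate`, `effector` and `effector_concentration_M`
#' are optional.  Write-then-read round-trips are exact to the
#' serialised precision (15 significant digits).
#'
#' @param path File path.
#' @param data A [titration_data()] (for `write_titration`).
#' @return `read_titration()` returns a [titration_data()];
#'   `write_titration()` returns `path` invisibly.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (i in which(is_meta)) {
    kv <- sub("^#\\s*", "", lines[i])
    m <- regmatches(kv, regexec("^([^=]+)=(.*)$", kv))[[1]]
    if (length(m) != 3L) {
      stop("malformed metadata at line ", i, " of ", path, ": '",
           lines[i], "'", call. = FALSE)
    }
    meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(meta$probe_total_M)) {
    stop("header of ", path, " lacks the required 'probe_total_M' key",
         call. = FALSE)
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2L) {
    stop("no data rows found in ", path, call. = FALSE)
  }
  df <- utils::read.csv(text = body, header = TRUE)
  need <- c("titrant_monomer_M", "delta_r")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  titration_data(
    probe_total = as.numeric(meta$probe_total_M),
    titrant_monomer_M = df$titrant_monomer_M,
    delta_r = df$delta_r,
    replicate_id = meta$replicate %||% "r1",
    effector = meta$effector %||% "apo",
    effector_concentration_M =
      as.numeric(meta$effector_concentration_M %||% NA)
  )
}

#' @rdname read_titration
#' @export
write_titration <- function(data, path) {
  stopifnot(inherits(data, "titration_data"))
  hdr <- c(
    sprintf("# probe_total_M=%.15g", data$probe_total),
    sprintf("# replicate=%s", data$replicate_id),
    sprintf("# effector=%s", data$effector),
    if (is.finite(data$effector_concentration_M))
      sprintf("# effector_concentration_M=%.15g",
              data$effector_concentration_M)
  )
  body <- c("titrant_monomer_M,delta_r",
            sprintf("%.15g,%.15g", data$titrant_monomer_M,
                    data$delta_r))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a structured result report
#'
#' Serialises a fit, coupling or breakpoint result (or any named list
#' of scalars) as JSON, embedding the package version and a hash of the
#' generating configuration so that reports are traceable.
#'
#' @param result A result object or named list.
#' @param path Output path.
#' @param config Optional configuration object included via its hash.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, config = NULL) {
  payload <- strip_classes(unclass(result))
  payload$package_version <-
    as.character(utils::packageVersion("anisofit"))
  if (!is.null(config)) {
    payload$config_hash <- config_hash(config)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small polynomial rolling hash; a traceability tag, not cryptography
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
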