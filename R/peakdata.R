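#' Construct a feature map (one LC-MS run)
#'
#' A feature map holds the detected features of a single run: retention time
#' in minutes, m/z in amu and an intensity per feature, together with run
#' metadata (polarity and whether the run is of labeled, un-labeled or mixed
#' material).
#'
#' @param features data.frame with columns `rt`, `mz`, `intensity` and
#'   optionally `id` (unique strings; generated if missing). Extra columns
#'   are preserved.
#' @param run_id Run identifier string.
#' @param polarity `"positive"`, `"negative"` or `"neutral"`.
#' @param label_status `"unlabeled"`, `"labeled"` or `"mixture"`.
#' @return An object of class `feature_map`.
#' @examples
#' fm <- feature_map(data.frame(rt = 1.2, mz = 315.17, intensity = 100),
#'                   run_id = "run1", polarity = "positive",
#'                   label_status = "unlabeled")
#' @export
feature_map <- function(features, run_id = "run",
                        polarity = c("positive", "negative", "neutral"),
                        label_status = c("unlabeled", "labeled", "mixture")) {
  polarity <- match.arg(polarity)
  label_status <- match.arg(label_status)
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(id = character(0), rt = numeric(0),
                           mz = numeric(0), intensity = numeric(0),
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    req <- c("rt", "mz", "intensity")
    miss <- setdiff(req, names(features))
    if (length(miss))
      stop("feature table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!"id" %in% names(features))
      features$id <- sprintf("%s_f%04d", run_id, seq_len(nrow(features)))
    features$id <- as.character(features$id)
    if (anyDuplicated(features$id))
      stop("feature ids must be unique within a run", call. = FALSE)
    if (any(!is.finite(features$mz)) || any(features$mz <= 0))
      stop("all m/z must be finite and > 0", call. = FALSE)
    if (any(!is.finite(features$rt)) || any(features$rt < 0))
      stop("all retention times must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(features$intensity)) || any(features$intensity < 0))
      stop("all intensities must be finite and >= 0", call. = FALSE)
    features <- features[, c("id", setdiff(names(features), "id")),
                         drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(run_id = run_id, polarity = polarity,
                 label_status = label_status, features = features),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> run '%s': %d features, %s mode, %s\n",
              x$run_id, nrow(x$features), x$polarity, x$label_status))
  if (nrow(x$features)) {
    cat(sprintf("  rt %.2f-%.2f min, m/z %.4f-%.4f, base peak %.4g\n",
                min(x$features$rt), max(x$features$rt),
                min(x$features$mz), max(x$features$mz),
                base_peak_intensity(x)))
  }
  invisible(x)
}

#' Base-peak intensity of a run
#'
#' @param map A `feature_map`.
#' @return Maximum feature intensity (the base peak); errors on an empty map.
#' @export
base_peak_intensity <- function(map) {
  stopifnot(inherits(map, "feature_map"))
  if (nrow(map$features) == 0L)
    stop("empty feature map has no base peak", call. = FALSE)
  max(map$features$intensity)
}

#' Relative intensity of a feature against the run's base peak
#'
#' The base peak of a run is 100 percent.
#'
#' @param map A `feature_map`.
#' @param id Feature id (or numeric row index).
#' @return Intensity in percent of the base peak.
#' @export
relative_intensity <- function(map, id) {
  stopifnot(inherits(map, "feature_map"))
  if (is.numeric(id)) {
    if (any(id < 1 | id > nrow(map$features)))
      stop("feature index out of range", call. = FALSE)
    ii <- id
  } else {
    ii <- match(as.character(id), map$features$id)
    if (anyNA(ii))
      stop("feature id not found in map: ",
           paste(id[is.na(ii)], collapse = ", "), call. = FALSE)
  }
  100 * map$features$intensity[ii] / base_peak_intensity(map)
}

#' Read a feature table from delimited text
#'
#' The canonical dialect is tab-separated UTF-8 with a header row containing
#' at least `rt_min`, `mz` and `intensity` (any column order). An `id` column
#' is used if present; extra columns are preserved. A column named `rt_sec`
#' is rejected: retention times are minutes throughout.
#'
#' @param path File path.
#' @param run_id,polarity,label_status Run metadata, see [feature_map()].
#' @param sep Field separator (default tab).
#' @return A `feature_map`.
#' @export
read_feature_table <- function(path, run_id = basename(path),
                               polarity = c("positive", "negative",
                                            "neutral"),
                               label_status = c("unlabeled", "labeled",
                                                "mixture"),
                               sep = "\t") {
  polarity <- match.arg(polarity)
  label_status <- match.arg(label_status)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if ("rt_sec" %in% names(raw))
    stop("column 'rt_sec' found: retention times must be minutes ",
         "('rt_min')", call. = FALSE)
  req <- c("rt_min", "mz", "intensity")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("feature table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) || anyNA(v))
      stop("non-numeric value in column '", col, "' at data row ",
           paste(utils::head(unique(c(bad, which(is.na(v)))), 3),
                 collapse = ", "), " of ", path, call. = FALSE)
    v
  }
  df <- data.frame(rt = num("rt_min"), mz = num("mz"),
                   intensity = num("intensity"), stringsAsFactors = FALSE)
  if ("id" %in% names(raw)) df$id <- raw[["id"]]
  extra <- setdiff(names(raw), c(req, "id"))
  for (cn in extra) df[[cn]] <- raw[[cn]]
  feature_map(df, run_id = run_id, polarity = polarity,
              label_status = label_status)
}

#' Write a feature table
#'
#' Writes the canonical tab-separated dialect read by [read_feature_table()]
#' (columns `rt_min`, `mz`, `intensity`, `id`, then any extras). Numeric
#' columns are written with full precision so read/write round-trips.
#'
#' @param map A `feature_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(map, path) {
  stopifnot(inherits(map, "feature_map"))
  df <- map$features
  out <- data.frame(rt_min = sprintf("%.17g", df$rt),
                    mz = sprintf("%.17g", df$mz),
                    intensity = sprintf("%.17g", df$intensity),
                    id = df$id, stringsAsFactors = FALSE)
  for (cn in setdiff(names(df), c("id", "rt", "mz", "intensity")))
    out[[cn]] <- as.character(df[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove compound-specific reference ions from a run
#'
#' Drops every sample feature that lies within both an m/z and a retention
#' time tolerance (inclusive) of any feature of a reference run, e.g. a
#' blank/compound-only measurement acquired to subtract compound-specific
#' ions before filtering. Survivor order is preserved.
#'
#' @param sample,reference `feature_map`s of the same polarity.
#' @param mz_tol m/z tolerance in amu.
#' @param rt_tol Retention-time tolerance in minutes.
#' @return The filtered sample `feature_map`.
#' @export
subtract_reference_ions <- function(sample, reference, mz_tol = 0.01,
                                    rt_tol = 0.1) {
  stopifnot(inherits(sample, "feature_map"),
            inherits(reference, "feature_map"))
  if (sample$polarity != reference$polarity)
    stop("sample and reference polarity differ", call. = FALSE)
  if (nrow(sample$features) == 0L || nrow(reference$features) == 0L)
    return(sample)
  s <- sample$features
  r <- reference$features
  hit <- vapply(seq_len(nrow(s)), function(i) {
    any(abs(r$mz - s$mz[i]) <= mz_tol & abs(r$rt - s$rt[i]) <= rt_tol)
  }, logical(1))
  out <- sample
  out$features <- s[!hit, , drop = FALSE]
  rownames(out$features) <- NULL
  out
}

#' Construct a centroided scan
#'
#' @param scan_time Scan time in minutes (>= 0).
#' @param mz,intensity Parallel centroid vectors; stored sorted by m/z.
#' @return An object of class `centroid_scan`.
#' @export
centroid_scan <- function(scan_time, mz = numeric(0),
                          intensity = numeric(0)) {
  if (!is.finite(scan_time) || scan_time < 0)
    stop("scan_time must be finite and >= 0", call. = FALSE)
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ", call. = FALSE)
  o <- order(mz)
  structure(list(scan_time = scan_time, mz = as.numeric(mz[o]),
                 intensity = as.numeric(intensity[o])),
            class = "centroid_scan")
}

#' Read centroided scans from a JSON-lines dump
#'
#' One JSON object per line with fields `scan_time` (minutes) and parallel
#' arrays `mz` and `intensity`. This is the dependency-free scan exchange
#' format; see [read_scans_mzml()] for mzML input.
#'
#' @param path File path.
#' @return List of `centroid_scan`, sorted by scan time.
#' @export
read_scans_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  scans <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    centroid_scan(x$scan_time, as.numeric(unlist(x$mz)),
                  as.numeric(unlist(x$intensity)))
  })
  scans[order(vapply(scans, `[[`, numeric(1), "scan_time"))]
}

#' Write centroided scans as JSON-lines
#'
#' @param scans List of `centroid_scan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scans_jsonl <- function(scans, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in scans) {
    writeLines(jsonlite::toJSON(list(scan_time = s$scan_time, mz = s$mz,
                                     intensity = s$intensity),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read centroided scans from an mzML file
#'
#' Requires the `mzR` package. Only centroided spectra are supported; scan
#' times are converted from seconds to minutes.
#'
#' @param path mzML file path.
#' @return List of `centroid_scan`, sorted by scan time.
#' @export
read_scans_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hd <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(seq_len(nrow(hd)), function(i) {
    centroid_scan(hd$retentionTime[i] / 60, pk[[i]][, 1], pk[[i]][, 2])
  })
  scans[order(vapply(scans, `[[`, numeric(1), "scan_time"))]
}
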