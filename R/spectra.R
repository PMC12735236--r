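#' Construct an MS/MS spectrum
#'
#' The unit object of networking and annotation: one negative-mode
#' product-ion spectrum per LC-MS feature.
#'
#' @param feature_id Unique feature identifier (MGF TITLE).
#' @param precursor_mz Precursor m/z in Da (> 0).
#' @param rt Retention time in minutes.
#' @param peaks Two-column numeric matrix or data.frame (mz, intensity).
#'   Peaks are sorted by m/z; exact duplicate m/z values are merged by
#'   summing their intensities.
#' @param charge Charge string, fixed to `"1-"` for this workflow.
#' @return An `msms_spectrum` object.
#' @export
msms_spectrum <- function(feature_id, precursor_mz, rt, peaks, charge = "1-") {
  stopifnot(length(feature_id) == 1L, length(precursor_mz) == 1L,
            length(rt) == 1L)
  if (!is.finite(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be positive for feature '", feature_id, "'")
  }
  peaks <- as.matrix(peaks)
  if (length(peaks) == 0L) {
    peaks <- matrix(numeric(0), ncol = 2)
  }
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)")
  colnames(peaks) <- c("mz", "intensity")
  if (any(peaks[, "intensity"] < 0)) {
    stop("negative peak intensity in feature '", feature_id, "'")
  }
  if (nrow(peaks)) {
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
    if (anyDuplicated(peaks[, "mz"])) {
      inten <- tapply(peaks[, "intensity"], peaks[, "mz"], sum)
      peaks <- cbind(mz = as.numeric(names(inten)),
                     intensity = as.numeric(inten))
    }
  }
  structure(
    list(feature_id = as.character(feature_id),
         precursor_mz = as.numeric(precursor_mz),
         rt = as.numeric(rt),
         charge = charge,
         peaks = peaks),
    class = "msms_spectrum"
  )
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat("<msms_spectrum> ", x$feature_id,
      sprintf("  precursor %.4f  rt %.2f min  %d peaks\n",
              x$precursor_mz, x$rt, nrow(x$peaks)), sep = "")
  invisible(x)
}

#' Construct a feature quantification table
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt`.
#' @param intensities Non-negative numeric matrix, features x samples.
#' @param samples Character vector of sample ids (column order preserved).
#' @param normalized Logical; normalized tables hold centred/scaled values
#'   and are exempt from the non-negativity check that applies to raw
#'   intensity tables.
#' @return A `feature_table` object.
#' @export
feature_table <- function(features, intensities, samples = colnames(intensities),
                          normalized = FALSE) {
  features <- as.data.frame(features)
  stopifnot(all(c("feature_id", "mz", "rt") %in% names(features)))
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features)) {
    stop("intensity rows (", nrow(intensities), ") != feature rows (",
         nrow(features), ")")
  }
  if (is.null(samples)) stop("sample ids are required")
  if (ncol(intensities) != length(samples)) {
    stop("intensity columns != number of samples")
  }
  if (!normalized && any(intensities < 0)) {
    stop("negative intensities are not allowed")
  }
  if (anyDuplicated(features$feature_id)) stop("duplicate feature ids")
  dimnames(intensities) <- list(features$feature_id, samples)
  structure(list(features = features, samples = samples,
                 intensities = intensities),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$intensities), " features x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Read an MGF file of MS/MS spectra
#'
#' Parses `BEGIN IONS`/`END IONS` blocks, honouring `TITLE` (feature id),
#' `PEPMASS`, `RTINSECONDS` (converted to minutes) and `CHARGE`; peak lines
#' are whitespace-separated (m/z, intensity) pairs.
#'
#' @param path Path to an MGF file.
#' @return List of [msms_spectrum] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) ||
      (length(begins) && any(ends < begins))) {
    stop("unbalanced BEGIN IONS/END IONS blocks in ", path)
  }
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("^[A-Z]+=", block)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[A-Z]+=", "", kv)
    fields <- stats::setNames(vals, keys)
    if (is.na(fields["PEPMASS"])) {
      stop("MGF block ", i, " is missing PEPMASS")
    }
    pep <- as.numeric(strsplit(fields[["PEPMASS"]], "\\s+")[[1]][1])
    title <- if (!is.na(fields["TITLE"])) fields[["TITLE"]] else paste0("spectrum_", i)
    rt <- if (!is.na(fields["RTINSECONDS"])) {
      as.numeric(fields[["RTINSECONDS"]]) / 60
    } else NA_real_
    charge <- if (!is.na(fields["CHARGE"])) fields[["CHARGE"]] else "1-"
    peak_lines <- block[!is_kv]
    peaks <- if (length(peak_lines)) {
      vals2 <- strsplit(peak_lines, "\\s+")
      if (any(lengths(vals2) < 2L)) {
        stop("malformed peak line in MGF block ", i)
      }
      m <- t(vapply(vals2, function(v) as.numeric(v[1:2]), numeric(2)))
      if (anyNA(m)) stop("non-numeric peak values in MGF block ", i)
      m
    } else matrix(numeric(0), ncol = 2)
    extra <- fields[setdiff(names(fields),
                            c("TITLE", "PEPMASS", "RTINSECONDS", "CHARGE"))]
    s <- msms_spectrum(title, pep, rt, peaks, charge)
    if (length(extra)) attr(s, "mgf_fields") <- as.list(extra)
    out[[i]] <- s
  }
  out
}

#' Write spectra to an MGF file
#'
#' Deterministic serialization: fixed field order, m/z at 4 decimal places,
#' intensities at 1; byte-identical across runs for identical input.
#'
#' @param spectra List of [msms_spectrum] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in spectra) {
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", s$feature_id),
      paste0("PEPMASS=", sprintf("%.4f", s$precursor_mz)),
      if (!is.na(s$rt)) paste0("RTINSECONDS=", sprintf("%.2f", s$rt * 60)),
      paste0("CHARGE=", s$charge)
    )
    extra <- attr(s, "mgf_fields")
    for (k in names(extra)) lines <- c(lines, paste0(k, "=", extra[[k]]))
    if (nrow(s$peaks)) {
      lines <- c(lines, sprintf("%.4f %.1f", s$peaks[, "mz"],
                                s$peaks[, "intensity"]))
    }
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a CSV feature quantification table
#'
#' Expected header: `feature_id, mz, rt`, then one column per sample.
#'
#' @param path Path to a CSV file.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(df)[1:3])) {
    stop("feature table must start with columns: feature_id, mz, rt")
  }
  samples <- names(df)[-(1:3)]
  inten <- as.matrix(df[, -(1:3), drop = FALSE])
  if (nrow(inten) == 0L) storage.mode(inten) <- "double"
  if (!is.numeric(inten)) stop("non-numeric intensities in ", path)
  if (anyNA(inten)) stop("missing intensities in ", path)
  if (any(inten < 0)) stop("negative intensities in ", path)
  feature_table(df[, need], inten, samples)
}

#' Write a feature table as CSV
#'
#' @param ft A [feature_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- cbind(ft$features[c("feature_id", "mz", "rt")],
              as.data.frame(ft$intensities, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
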