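#' Read a spectral library of authentic standards
#'
#' The library is an MGF file whose blocks carry `NAME=` and `FORMULA=`
#' headers in addition to the usual fields; the neutral formula provides
#' the theoretical \eqn{[M-H]^-} m/z for precursor matching.
#'
#' @param path Path to a library MGF file.
#' @return List of `library_entry` objects: `name`, `neutral_formula`,
#'   `rt` (minutes), `reference` (an [msms_spectrum] of reference peaks),
#'   `theoretical_mz`.
#' @export
read_spectral_library <- function(path) {
  spectra <- read_mgf(path)
  lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    extra <- attr(s, "mgf_fields")
    if (is.null(extra$NAME) || is.null(extra$FORMULA)) {
      stop("library block ", i, " lacks NAME/FORMULA headers")
    }
    f <- parse_formula(extra$FORMULA)
    th <- mz_deprotonated(f)
    if (abs(ppm_error(s$precursor_mz, th)) > 5) {
      stop("library entry '", extra$NAME, "': precursor ",
           sprintf("%.4f", s$precursor_mz), " is >5 ppm from computed [M-H]- ",
           sprintf("%.4f", th))
    }
    structure(list(name = extra$NAME, neutral_formula = f, rt = s$rt,
                   reference = s, theoretical_mz = th),
              class = "library_entry")
  })
}

#' Identify features against a library of authentic standards
#'
#' A feature matches an entry when its precursor m/z is within `ppm_tol`
#' of the entry's computed \eqn{[M-H]^-} m/z, its retention time is within
#' `rt_tol` minutes, and the modified cosine between the feature spectrum
#' and the reference spectrum is at least `cosine_min` — the
#' RT + exact-mass + MS/MS criterion used for unambiguous dereplication.
#' Isobaric standards at distinct retention times (e.g. E/Z isomer pairs)
#' are separated by the RT window.
#'
#' @param spectra List of [msms_spectrum] objects.
#' @param library List of entries from [read_spectral_library()].
#' @param ppm_tol Precursor tolerance in ppm (default 10).
#' @param rt_tol Retention-time tolerance in minutes (default 0.2).
#' @param cosine_min Minimum modified cosine (default 0.7).
#' @param fragment_tol Fragment tolerance for the cosine, Da.
#' @return data.frame of identifications: `feature_id`, `library_name`,
#'   `ppm_error`, `rt_delta`, `cosine`, ranked within each feature by
#'   cosine (desc), then |ppm| (asc), then library name.
#' @export
match_library <- function(spectra, library, ppm_tol = 10, rt_tol = 0.2,
                          cosine_min = 0.7, fragment_tol = 0.02) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  rows <- list()
  for (s in spectra) {
    for (entry in library) {
      ppm <- ppm_error(s$precursor_mz, entry$theoretical_mz)
      if (abs(ppm) > ppm_tol) next
      rt_delta <- s$rt - entry$rt
      if (is.na(rt_delta) || abs(rt_delta) > rt_tol) next
      if (nrow(s$peaks) == 0L || nrow(entry$reference$peaks) == 0L) next
      mc <- modified_cosine(s, entry$reference, fragment_tol = fragment_tol)
      if (mc$score < cosine_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = s$feature_id, library_name = entry$name,
        ppm_error = ppm, rt_delta = rt_delta, cosine = mc$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(feature_id = character(0), library_name = character(0),
                      ppm_error = numeric(0), rt_delta = numeric(0),
                      cosine = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$feature_id, -out$cosine, abs(out$ppm_error),
            out$library_name), , drop = FALSE]
}
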