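# Seeded synthetic-corpus generator.
#
# Instrument data for this kind of study are rarely redistributable, so
# the pipeline is exercised on a generated stand-in with the structure the
# analysis assumes: ~9 extracts in two chemotype groups, features mostly
# in the m/z 300-550 window, MS/MS spectra built from the diagnostic
# neutral-loss grammar of each structural class, and chemotype-specific
# abundance contrasts. Every template formula comes from a printed
# composition of a real isomalabaricane or related lipid, so generated
# precursors are chemically plausible.

# per-class spectral templates: formula pool, retention window (min),
# fragment grammar (loss chains and/or anion compositions with relative
# intensities), and chemotype enrichment
.CLASS_TEMPLATES <- list(
  SC_ACID = list(
    formulas = c("C25H34O4", "C20H28O4", "C27H36O4", "C22H30O4"),
    rt_range = c(12.0, 14.2),
    losses = list(list(chain = c("CO2"), rel = 100),
                  list(chain = c("CO2", "CH4"), rel = 85),
                  list(chain = c("C6H6O2"), rel = 40),
                  list(chain = c("C5H8O"), rel = 25)),
    ions = list(),
    enriched = "A"
  ),
  CORE_RAA = list(
    formulas = c("C30H40O4", "C30H42O4"),
    rt_range = c(16.2, 17.5),
    losses = list(list(chain = c("CO2"), rel = 100),
                  list(chain = c("CO2", "CH4"), rel = 90)),
    ions = list(list(formula = "C20H29O2", rel = 60),
                list(formula = "C19H25O2", rel = 55),
                list(formula = "C17H25O2", rel = 50),
                list(formula = "C16H21O2", rel = 40),
                list(formula = "C15H17O2", rel = 30)),
    enriched = "A"
  ),
  GLYCOSIDE = list(
    formulas = c("C44H73NO14", "C43H71NO14", "C44H73NO13"),
    rt_range = c(9.0, 10.7),
    losses = list(list(chain = c("C8H13NO5"), rel = 70),
                  list(chain = c("C8H13NO5", "C6H10O5"), rel = 60)),
    ions = list(list(formula = "C8H12NO5", rel = 100),
                list(formula = "C10H16NO7", rel = 45)),
    enriched = "A"
  ),
  NITROGENOUS = list(
    formulas = c("C22H31NO4", "C22H33NO5", "C22H31NO5", "C22H35NO5"),
    rt_range = c(13.8, 15.3),
    losses = list(list(chain = c("CO2"), rel = 100),
                  list(chain = c("CO2", "CH4"), rel = 80),
                  list(chain = c("CO2", "C2H3NO"), rel = 50),
                  list(chain = c("CO2", "CH4", "C2H3NO"), rel = 45)),
    ions = list(),
    enriched = "A"
  ),
  CORE_3OH_4COOH = list(
    formulas = c("C27H36O5", "C30H42O4", "C28H38O5"),
    rt_range = c(10.5, 11.2),
    losses = list(list(chain = c("H2O"), rel = 40),
                  list(chain = c("CO"), rel = 10),
                  list(chain = c("CO2"), rel = 30),
                  list(chain = c("CO2", "H2O"), rel = 100),
                  list(chain = c("CO2", "H2O", "H2O"), rel = 35),
                  list(chain = c("CO2", "H2O", "H2O", "CH4"), rel = 20)),
    ions = list(list(formula = "C19H25O", rel = 55),
                list(formula = "C18H25O", rel = 50),
                list(formula = "C15H19O", rel = 45),
                list(formula = "C13H11O", rel = 40)),
    enriched = "B"
  ),
  ACETOXY_MOD = list(
    formulas = c("C32H44O5", "C29H38O6", "C32H44O7"),
    rt_range = c(13.8, 20.3),
    losses = list(list(chain = c("CO2"), rel = 100),
                  list(chain = c("C2H4O2"), rel = 85),
                  list(chain = c("CO2", "C2H4O"), rel = 50),
                  list(chain = c("C2H4O2", "C2H4O"), rel = 40),
                  list(chain = c("C6H6O2"), rel = 30),
                  list(chain = c("C6H6O2", "C2H4O"), rel = 25)),
    ions = list(),
    enriched = "B"
  ),
  LYSO_PI = list(
    formulas = c("C25H49O11P", "C27H53O11P"),
    rt_range = c(8.0, 9.5),
    losses = list(list(chain = c("C6H10O5"), rel = 50),
                  list(chain = c("C6H12O6"), rel = 35)),
    ions = list(list(formula = "C6H12O9P", rel = 100),
                list(formula = "C6H10O8P", rel = 70),
                list(formula = "C6H8O7P", rel = 45)),
    enriched = "none"
  )
)

#' Configuration of the synthetic corpus
#'
#' Defaults emulate the study conditions the pipeline is built for: nine
#' extracts split 6/3 into chemotypes A and B, features concentrated in
#' the m/z 300-550 window, 0.005 Da m/z jitter, five noise peaks per
#' spectrum at up to 5\% of the base peak, and a chemotype abundance
#' contrast of 1.5 log10 units for enriched feature classes.
#'
#' @param n_samples Number of samples (default 9).
#' @param chemotype Named character vector assigning each sample to
#'   `"A"` or `"B"`; default six A then three B.
#' @param n_features_per_class Named integer vector, class id -> feature
#'   count.
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da.
#' @param noise_peaks Noise peaks per spectrum.
#' @param abundance_shift Chemotype mean shift, log10 units.
#' @param abundance_mu,abundance_sd Base-10 log-intensity mean/SD of
#'   per-feature abundance levels.
#' @param within_sd Within-chemotype log10 intensity SD.
#' @param intensity_noise_sdlog Log-normal multiplicative noise (natural
#'   log SD) on fragment intensities.
#' @param rng_seed Integer seed; the corpus is a pure function of this
#'   configuration.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_samples = 9,
                          chemotype = NULL,
                          n_features_per_class = c(
                            SC_ACID = 8L, CORE_RAA = 6L, GLYCOSIDE = 5L,
                            NITROGENOUS = 4L, CORE_3OH_4COOH = 8L,
                            ACETOXY_MOD = 6L, LYSO_PI = 5L),
                          mz_jitter_sd = 0.005,
                          noise_peaks = 5L,
                          abundance_shift = 1.5,
                          abundance_mu = 6, abundance_sd = 0.2,
                          within_sd = 0.25,
                          intensity_noise_sdlog = 0.2,
                          rng_seed = 1L) {
  if (is.null(chemotype)) {
    ids <- sprintf("sample_%02d", seq_len(n_samples))
    n_b <- max(1L, round(n_samples / 3))
    chemotype <- stats::setNames(
      c(rep("A", n_samples - n_b), rep("B", n_b)), ids)
  }
  if (length(chemotype) != n_samples) {
    stop("chemotype assignment must cover all ", n_samples, " samples")
  }
  if (!all(chemotype %in% c("A", "B"))) stop("chemotypes must be 'A' or 'B'")
  bad <- setdiff(names(n_features_per_class), names(.CLASS_TEMPLATES))
  if (length(bad)) stop("unknown class id(s): ", paste(bad, collapse = ", "))
  if (any(n_features_per_class < 1)) stop("feature counts must be positive")
  if (mz_jitter_sd < 0) stop("mz_jitter_sd must be >= 0")
  if (noise_peaks < 0) stop("noise_peaks must be >= 0")
  structure(list(n_samples = n_samples, chemotype = chemotype,
                 n_features_per_class = n_features_per_class,
                 mz_jitter_sd = mz_jitter_sd,
                 noise_peaks = as.integer(noise_peaks),
                 abundance_shift = abundance_shift,
                 abundance_mu = abundance_mu, abundance_sd = abundance_sd,
                 within_sd = within_sd,
                 intensity_noise_sdlog = intensity_noise_sdlog,
                 rng_seed = as.integer(rng_seed)),
            class = "corpus_config")
}

#' Generate a synthetic MS/MS corpus
#'
#' Builds, for each feature, a class-template MS/MS spectrum (diagnostic
#' peaks computed exactly from the class's loss chains and fragment
#' compositions, then jittered), a per-sample abundance row from a
#' log-normal model with a chemotype-specific mean shift for enriched
#' classes, and a ground-truth record. Fully reproducible: identical
#' configurations give byte-identical output files.
#'
#' @param config A [corpus_config()].
#' @param dir Optional output directory; when given, writes `corpus.mgf`,
#'   `features.csv` and `ground_truth.json` there.
#' @return List with `spectra` (list of [msms_spectrum]), `table`
#'   (a [feature_table]), `truth` (data.frame: `feature_id`, `class_id`,
#'   `formula`, `enriched`), and `paths` when files were written.
#' @export
generate_corpus <- function(config = corpus_config(), dir = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$rng_seed)

  samples <- names(config$chemotype)
  spectra <- list()
  feat_rows <- list()
  truth_rows <- list()
  inten_rows <- list()
  idx <- 0L
  for (class_id in names(config$n_features_per_class)) {
    tmpl <- .CLASS_TEMPLATES[[class_id]]
    n_feat <- config$n_features_per_class[[class_id]]
    for (f in seq_len(n_feat)) {
      idx <- idx + 1L
      fid <- sprintf("F%03d_%s", idx, class_id)
      formula <- tmpl$formulas[((f - 1L) %% length(tmpl$formulas)) + 1L]
      prec_true <- mz_deprotonated(formula)
      prec <- prec_true + stats::rnorm(1, 0, config$mz_jitter_sd)
      rt <- stats::runif(1, tmpl$rt_range[1], tmpl$rt_range[2])

      mzs <- c(
        vapply(tmpl$losses, function(L)
          prec - sum(vapply(L$chain, monoisotopic_mass, numeric(1))),
          numeric(1)),
        vapply(tmpl$ions, function(I) anion_mz(I$formula), numeric(1)))
      rels <- c(vapply(tmpl$losses, function(L) L$rel, numeric(1)),
                vapply(tmpl$ions, function(I) I$rel, numeric(1)))
      mzs <- mzs + stats::rnorm(length(mzs), 0, config$mz_jitter_sd)
      inten <- rels * 10 *
        exp(stats::rnorm(length(rels), 0, config$intensity_noise_sdlog))
      if (config$noise_peaks > 0) {
        nmz <- stats::runif(config$noise_peaks, 80, prec - 1)
        nint <- stats::runif(config$noise_peaks, 0, 0.05) * max(inten)
        mzs <- c(mzs, nmz); inten <- c(inten, nint)
      }
      spectra[[idx]] <- msms_spectrum(fid, prec, rt, cbind(mzs, inten))

      shift <- ifelse(config$chemotype == tmpl$enriched,
                      config$abundance_shift, 0)
      if (tmpl$enriched == "none") shift <- rep(0, length(samples))
      mu_f <- stats::rnorm(1, config$abundance_mu, config$abundance_sd)
      logi <- mu_f + shift + stats::rnorm(length(samples), 0, config$within_sd)
      inten_rows[[idx]] <- 10^logi
      feat_rows[[idx]] <- data.frame(feature_id = fid, mz = prec, rt = rt,
                                     stringsAsFactors = FALSE)
      truth_rows[[idx]] <- data.frame(feature_id = fid, class_id = class_id,
                                      formula = formula,
                                      enriched = tmpl$enriched,
                                      stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feat_rows)
  truth <- do.call(rbind, truth_rows)
  intensities <- do.call(rbind, inten_rows)
  colnames(intensities) <- samples
  tab <- feature_table(features, round(intensities, 2), samples)

  out <- list(spectra = spectra, table = tab, truth = truth,
              chemotype = config$chemotype)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("corpus.mgf", "features.csv",
                              "ground_truth.json"))
    write_mgf(spectra, paths[1])
    write_feature_table(tab, paths[2])
    jsonlite::write_json(truth, paths[3], dataframe = "rows", pretty = TRUE,
                         digits = NA)
    out$paths <- stats::setNames(paths, c("mgf", "csv", "truth"))
  }
  out
}

#' The printed relative-content matrix of the 16 authentic standards
#'
#' The in-study data packaged with this repository: retention times,
#' measured \eqn{[M-H]^-} m/z and per-specimen relative contents (percent,
#' normalized to each compound's maximum across samples) of the sixteen
#' isomalabaricane standards identified across the nine sponge extracts.
#'
#' @return A [feature_table] of 16 compounds x 9 specimens; the
#'   `features` data.frame carries `compound` names and neutral `formula`
#'   strings alongside `feature_id`, `mz` (measured) and `rt`.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_relative_content.csv",
                      package = "isomalnet")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  features <- data.frame(feature_id = df$compound, mz = df$mz_measured,
                         rt = df$rt, compound = df$compound,
                         formula = df$formula, stringsAsFactors = FALSE)
  inten <- as.matrix(df[, -(1:4), drop = FALSE])
  feature_table(features, inten, colnames(inten))
}
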