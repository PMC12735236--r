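# Diagnostic-fragmentation rule engine.
#
# The structural-class vocabulary of negative-mode isomalabaricane MS/MS:
# side-chain acids lose CO2 then CO2+CH4; 3-hydroxy-4-carboxy cores are
# dominated by the CO2+H2O loss and never lose CO2+CH4; acetates show an
# acetic-acid loss and series pairs offset by 44 Da; glycosides peel sugar
# units off as Y-ions; nitrogenous congeners betray themselves through the
# anion nitrogen rule and a 57.02 Da (C2H3NO) loss; lyso-PI lipids print
# the 259/241/223 inositol-phosphate triad. Rules live in an editable JSON
# file so chemists can extend the grammar without touching code.

#' Load structural-class fragmentation rules
#'
#' @param path Path to a rules JSON file; defaults to the rule set shipped
#'   with the package.
#' @return A `class_rules` list; one element per class, each holding its
#'   rule list. Scoring-rule weights are validated to sum to 1 per class.
#' @export
load_class_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_rules.json", package = "isomalnet")
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  classes <- raw$classes
  out <- list()
  for (cl in classes) {
    w <- 0
    for (r in cl$rules) {
      forb <- isTRUE(r$forbidden)
      if (forb && isTRUE(r$required)) {
        stop("class ", cl$class_id, ": a rule cannot be both required and forbidden")
      }
      if (!forb) {
        if (is.null(r$weight) || r$weight <= 0) {
          stop("class ", cl$class_id, ": scoring rule '", r$label,
               "' needs a positive weight")
        }
        w <- w + r$weight
      }
    }
    if (abs(w - 1) > 1e-9) {
      stop("class ", cl$class_id, ": scoring weights sum to ", w, ", not 1")
    }
    out[[cl$class_id]] <- cl
  }
  structure(out, class = "class_rules")
}

#' Detect diagnostic neutral-loss chains in a spectrum
#'
#' For each loss chain the target m/z is the precursor minus the summed
#' monoisotopic masses of the chain's neutral formulas; the match is the
#' most intense peak within `tol` that clears the relative-intensity
#' floor.
#'
#' @param s An [msms_spectrum].
#' @param losses List of loss chains; each chain is a character vector of
#'   neutral formulas, e.g. `list("CO2", c("CO2", "CH4"))`.
#' @param tol Match tolerance in Da (default 0.02).
#' @param min_rel_intensity Diagnostic floor as a fraction of the base
#'   peak (default 0.01).
#' @return data.frame with one row per chain: `chain`, `target_mz`,
#'   `matched`, `observed_mz`, `error_da`, `rel_intensity`,
#'   `intensity_rank`.
#' @export
detect_losses <- function(s, losses, tol = 0.02, min_rel_intensity = 0.01) {
  stopifnot(inherits(s, "msms_spectrum"), tol > 0)
  chains <- vapply(losses, function(ch) paste(ch, collapse = "+"), character(1))
  n <- length(losses)
  out <- data.frame(chain = chains, target_mz = NA_real_, matched = FALSE,
                    observed_mz = NA_real_, error_da = NA_real_,
                    rel_intensity = NA_real_, intensity_rank = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  for (k in seq_len(n)) {
    loss_mass <- sum(vapply(losses[[k]], monoisotopic_mass, numeric(1)))
    out$target_mz[k] <- s$precursor_mz - loss_mass
  }
  if (!nrow(s$peaks)) return(out)
  base <- max(s$peaks[, "intensity"])
  if (base <= 0) return(out)
  rel <- s$peaks[, "intensity"] / base
  ranks <- rank(-s$peaks[, "intensity"], ties.method = "min")
  for (k in seq_len(n)) {
    d <- abs(s$peaks[, "mz"] - out$target_mz[k])
    cand <- which(d <= tol & rel >= min_rel_intensity)
    if (!length(cand)) next
    hit <- cand[which.max(s$peaks[cand, "intensity"])]
    out$matched[k] <- TRUE
    out$observed_mz[k] <- s$peaks[hit, "mz"]
    out$error_da[k] <- s$peaks[hit, "mz"] - out$target_mz[k]
    out$rel_intensity[k] <- rel[hit]
    out$intensity_rank[k] <- as.integer(ranks[hit])
  }
  out
}

# nominal ion-series detector: a target integer is hit when some peak
# rounds to it within a +-guard of the integer (excludes mid-decade
# artifacts) and clears the intensity floor
.detect_series <- function(s, nominal_mzs, guard = 0.3,
                           min_rel_intensity = 0.01) {
  if (!nrow(s$peaks)) {
    return(data.frame(nominal = as.integer(nominal_mzs), matched = FALSE,
                      observed_mz = NA_real_))
  }
  base <- max(s$peaks[, "intensity"])
  rel <- if (base > 0) s$peaks[, "intensity"] / base else rep(0, nrow(s$peaks))
  res <- lapply(as.integer(nominal_mzs), function(t) {
    d <- abs(s$peaks[, "mz"] - t)
    cand <- which(d <= guard & rel >= min_rel_intensity)
    if (!length(cand)) {
      data.frame(nominal = t, matched = FALSE, observed_mz = NA_real_)
    } else {
      hit <- cand[which.max(s$peaks[cand, "intensity"])]
      data.frame(nominal = t, matched = TRUE, observed_mz = s$peaks[hit, "mz"])
    }
  })
  do.call(rbind, res)
}

# parallel-series detector: count peak pairs separated by a fixed neutral
# offset (default C2H4O, 44.0262 Da) within tolerance
.detect_parallel_series <- function(s, offset_formula = "C2H4O", tol = 0.02,
                                    min_rel_intensity = 0.01) {
  if (nrow(s$peaks) < 2) return(list(n_pairs = 0L, pairs = NULL))
  off <- monoisotopic_mass(offset_formula)
  base <- max(s$peaks[, "intensity"])
  keep <- s$peaks[, "intensity"] / base >= min_rel_intensity
  mz <- s$peaks[keep, "mz"]
  if (length(mz) < 2) return(list(n_pairs = 0L, pairs = NULL))
  dm <- abs(outer(mz, mz, "-") - off)
  hits <- which(dm <= tol, arr.ind = TRUE)
  if (!nrow(hits)) return(list(n_pairs = 0L, pairs = NULL))
  list(n_pairs = nrow(hits),
       pairs = cbind(high = mz[hits[, 1]], low = mz[hits[, 2]]))
}

#' Nominal-mass parity of a precursor ion (anion nitrogen rule)
#'
#' For CHNO compounds an even nominal \eqn{[M-H]^-} mass indicates an odd
#' nitrogen count (the neutral has odd nominal mass).
#'
#' @param precursor_mz Precursor m/z (> 0 expected; values that round to
#'   zero are flagged with a warning).
#' @return List with `nominal`, `parity` (`"even"`/`"odd"`), and
#'   `n_odd_hint` (`TRUE` when the parity suggests odd nitrogen count).
#' @export
nitrogen_parity <- function(precursor_mz) {
  nominal <- nominal_mass(precursor_mz)
  if (nominal < 1) warning("precursor m/z rounds to ", nominal,
                           "; parity hint is not meaningful")
  even <- nominal %% 2L == 0L
  list(nominal = nominal, parity = if (even) "even" else "odd",
       n_odd_hint = even)
}

.evaluate_rule <- function(rule, s, formula, tol, guard, floor_) {
  type <- rule$type
  if (type == "loss") {
    chain <- unlist(rule$chain)
    hit <- detect_losses(s, list(chain), tol = tol,
                         min_rel_intensity = floor_)
    ok <- hit$matched[1]
    if (ok && !is.null(rule$max_intensity_rank)) {
      ok <- hit$intensity_rank[1] <= rule$max_intensity_rank
    }
    ev <- if (isTRUE(ok)) {
      sprintf("%s@%.4f(%+.4f)", rule$label, hit$observed_mz[1], hit$error_da[1])
    } else NA_character_
    list(satisfied = isTRUE(ok), evidence = ev)
  } else if (type == "series") {
    hits <- .detect_series(s, unlist(rule$nominal_mzs), guard = guard,
                           min_rel_intensity = floor_)
    ok <- sum(hits$matched) >= rule$min_hits
    ev <- if (ok) {
      obs <- hits[hits$matched, ]
      sprintf("%s@{%s}", rule$label,
              paste(sprintf("%.4f", obs$observed_mz), collapse = ","))
    } else NA_character_
    list(satisfied = ok, evidence = ev)
  } else if (type == "parallel_series") {
    ps <- .detect_parallel_series(s, rule$offset_formula, tol = tol,
                                  min_rel_intensity = floor_)
    ok <- ps$n_pairs >= rule$min_pairs
    ev <- if (ok) sprintf("%s:%d pairs", rule$label, ps$n_pairs) else NA_character_
    list(satisfied = ok, evidence = ev)
  } else if (type == "parity") {
    par <- nitrogen_parity(s$precursor_mz)
    ok <- par$n_odd_hint ||
      (!is.null(formula) && "N" %in% names(.as_counts(formula)))
    ev <- if (ok) sprintf("%s (nominal %d)", rule$label, par$nominal) else NA_character_
    list(satisfied = ok, evidence = ev)
  } else {
    stop("unknown rule type '", type, "'")
  }
}

#' Annotate a spectrum with structural-class hypotheses
#'
#' Each class is scored as the weight-sum of its satisfied rules; the
#' score is zeroed when any forbidden rule fires or any required rule
#' fails. Classes are not mutually exclusive: a side-chain acid with an
#' RAA-type core legitimately scores both classes. Hypotheses with score
#' >= `score_min` are returned ranked by score (descending), ties broken
#' by class id.
#'
#' @param s An [msms_spectrum].
#' @param formula Optional neutral [elemental formula][parse_formula] of
#'   the feature (used by the nitrogen-parity rule).
#' @param rules A [load_class_rules()] rule set (default: shipped rules).
#' @param tol Fragment-match tolerance in Da.
#' @param guard Nominal-series guard band in Da.
#' @param min_rel_intensity Diagnostic intensity floor (fraction of base peak).
#' @param score_min Minimum reported hypothesis score (default 0.5).
#' @return An `annotation_result`: `feature_id` plus a `hypotheses`
#'   data.frame (`class_id`, `score`, `evidence`). When no class reaches
#'   `score_min` the single row carries the `UNCLASSIFIED` sentinel.
#' @export
classify <- function(s, formula = NULL, rules = load_class_rules(),
                     tol = 0.02, guard = 0.3, min_rel_intensity = 0.01,
                     score_min = 0.5) {
  stopifnot(inherits(s, "msms_spectrum"))
  rows <- list()
  for (cl in rules) {
    score <- 0
    evid <- character(0)
    dead <- FALSE
    for (r in cl$rules) {
      res <- .evaluate_rule(r, s, formula, tol, guard, min_rel_intensity)
      if (isTRUE(r$forbidden)) {
        if (res$satisfied) { dead <- TRUE; break }
        next
      }
      if (isTRUE(r$required) && !res$satisfied) { dead <- TRUE; break }
      if (res$satisfied) {
        score <- score + r$weight
        evid <- c(evid, res$evidence)
      }
    }
    score <- round(score, 9)  # weight sums must compare exactly for ranking
    if (!dead && score >= score_min) {
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = cl$class_id, score = score,
        evidence = paste(evid, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  hyp <- if (length(rows)) {
    h <- do.call(rbind, rows)
    h <- h[order(-h$score, h$class_id), , drop = FALSE]
    rownames(h) <- NULL
    h
  } else {
    data.frame(class_id = "UNCLASSIFIED", score = 0, evidence = "",
               stringsAsFactors = FALSE)
  }
  structure(list(feature_id = s$feature_id, hypotheses = hyp),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation> ", x$feature_id, "\n", sep = "")
  print(x$hypotheses[, c("class_id", "score")])
  invisible(x)
}

#' Detect typed analog relations between features
#'
#' Pairs features whose composition difference matches a known structural
#' modification: acetylation of a 3-keto (`+C2H4O`, retention extended by
#' roughly 3 min) or 3-hydroxy (`+C2H2O`, same window) position, double
#' bond reduction (`+H2`), hydration/extra hydroxyl (`+H2O`), and
#' constitutional/geometric isomerism (same formula, distinct retention
#' time). Each unordered pair is reported once, with `id_a` the lighter
#' (or earlier-eluting, for isomers) partner.
#'
#' @param features data.frame with columns `feature_id`, `formula`
#'   (strings; `NA` allowed), `rt` (minutes). When a formula is missing a
#'   column `mz` is used and matched by mass within `mz_tol`.
#' @param acetyl_rt_window Retention-shift window (min) for acetylation.
#' @param isomer_rt_min Minimum RT separation (min) to call isomers.
#' @param mz_tol Mass tolerance (Da) for formula-free matching.
#' @return data.frame: `id_a`, `id_b`, `relation`, `delta_formula`,
#'   `delta_rt`.
#' @export
pair_analogs <- function(features, acetyl_rt_window = c(2.5, 3.5),
                         isomer_rt_min = 0.05, mz_tol = 0.005) {
  features <- as.data.frame(features)
  stopifnot(all(c("feature_id", "rt") %in% names(features)))
  if (is.null(features$formula)) features$formula <- NA_character_
  n <- nrow(features)
  mass_of <- function(i) {
    if (!is.na(features$formula[i])) {
      monoisotopic_mass(features$formula[i])
    } else features$mz[i]
  }
  deltas <- list(
    ACETYL_OF_KETO = "C2H4O",
    ACETYL_OF_HYDROXY = "C2H2O",
    DIHYDRO = "H2",
    HYDRATE_OR_OH = "H2O"
  )
  delta_mass <- vapply(deltas, monoisotopic_mass, numeric(1))
  rows <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        mi <- mass_of(i); mj <- mass_of(j)
        lo <- if (mi <= mj) i else j
        hi <- if (mi <= mj) j else i
        dm <- abs(mj - mi)
        both_f <- !is.na(features$formula[i]) && !is.na(features$formula[j])
        rel <- NA_character_; dformula <- NA_character_
        if (both_f) {
          diff <- tryCatch(
            format(formula_subtract(features$formula[hi], features$formula[lo])),
            error = function(e) NA_character_)
          if (!is.na(diff)) {
            if (diff == "") {
              if (abs(features$rt[i] - features$rt[j]) >= isomer_rt_min) {
                rel <- "ISOMER_OF"; dformula <- ""
              }
            } else {
              hitn <- names(deltas)[vapply(deltas, function(d)
                format(parse_formula(d)) == diff, logical(1))]
              if (length(hitn)) { rel <- hitn[1]; dformula <- diff }
            }
          }
        } else {
          if (dm <= mz_tol) {
            if (abs(features$rt[i] - features$rt[j]) >= isomer_rt_min) {
              rel <- "ISOMER_OF"; dformula <- ""
            }
          } else {
            k <- which(abs(delta_mass - dm) <= mz_tol)
            if (length(k)) { rel <- names(deltas)[k[1]]; dformula <- deltas[[k[1]]] }
          }
        }
        if (is.na(rel)) next
        drt <- features$rt[hi] - features$rt[lo]
        if (rel %in% c("ACETYL_OF_KETO", "ACETYL_OF_HYDROXY") &&
            (drt < acetyl_rt_window[1] || drt > acetyl_rt_window[2])) next
        if (rel == "ISOMER_OF" && features$rt[lo] > features$rt[hi]) {
          tmp <- lo; lo <- hi; hi <- tmp
          drt <- -drt
        }
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = features$feature_id[lo], id_b = features$feature_id[hi],
          relation = rel, delta_formula = dformula, delta_rt = drt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      relation = character(0), delta_formula = character(0),
                      delta_rt = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$id_a, out$id_b, out$relation), , drop = FALSE]
}

#' Write annotation results as CSV
#'
#' @param annotations List of `annotation_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    h <- a$hypotheses
    data.frame(feature_id = a$feature_id, rank = seq_len(nrow(h)),
               class_id = h$class_id, score = h$score,
               evidence = h$evidence, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
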