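#' Modified cosine similarity between two MS/MS spectra
#'
#' The similarity kernel of feature-based molecular networking. Peaks of
#' `a` may pair with peaks of `b` either directly (offset 0) or shifted by
#' the precursor mass difference \eqn{\Delta = prec(b) - prec(a)}, so that
#' analogs differing by a single modification still score highly. Each
#' peak is used at most once; pairs are chosen greedily in order of
#' decreasing product of the L2-normalized square-root intensities (ties
#' broken by the lower m/z in `a`, then in `b`). The score is the sum of
#' the matched normalized products, which lies in \[0, 1\] and equals 1
#' for identical spectra.
#'
#' The shifted channel only opens when \eqn{|\Delta|} exceeds
#' `precursor_tol`; precursors closer than that are treated as equal.
#'
#' @param a,b [msms_spectrum] objects with at least one peak each.
#' @param fragment_tol Fragment matching tolerance in Da (default 0.02).
#' @param precursor_tol Parent-mass tolerance in Da (default 0.01).
#' @return List with `score` (numeric in \[0,1\]) and `n_matched`
#'   (number of matched peak pairs).
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.02, precursor_tol = 0.01) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L) {
    stop("modified_cosine requires non-empty peak lists")
  }
  ua <- sqrt(a$peaks[, "intensity"])
  ub <- sqrt(b$peaks[, "intensity"])
  na_ <- sqrt(sum(ua^2)); nb_ <- sqrt(sum(ub^2))
  if (na_ == 0 || nb_ == 0) return(list(score = 0, n_matched = 0L))
  ua <- ua / na_; ub <- ub / nb_
  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  delta <- b$precursor_mz - a$precursor_mz
  offsets <- 0
  if (abs(delta) > precursor_tol) offsets <- c(0, delta)

  cand_i <- integer(0); cand_j <- integer(0)
  for (off in offsets) {
    dm <- abs(outer(mza + off, mzb, "-"))
    hits <- which(dm <= fragment_tol, arr.ind = TRUE)
    if (nrow(hits)) {
      cand_i <- c(cand_i, hits[, 1]); cand_j <- c(cand_j, hits[, 2])
    }
  }
  if (!length(cand_i)) return(list(score = 0, n_matched = 0L))
  dup <- duplicated(cbind(cand_i, cand_j))
  cand_i <- cand_i[!dup]; cand_j <- cand_j[!dup]

  prod <- ua[cand_i] * ub[cand_j]
  ord <- order(-prod, mza[cand_i], mzb[cand_j])
  used_a <- logical(length(mza)); used_b <- logical(length(mzb))
  score <- 0; n_matched <- 0L
  for (k in ord) {
    i <- cand_i[k]; j <- cand_j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    score <- score + prod[k]
    n_matched <- n_matched + 1L
  }
  list(score = min(score, 1), n_matched = n_matched)
}
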