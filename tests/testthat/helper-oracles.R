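# Independent oracles used to cross-check the implementation. These are
# deliberately written against different algorithms than the package code:
# exhaustive search instead of greedy matching, union-find instead of
# igraph components, nested loops instead of a vectorized lattice.

# exhaustive maximum-weight one-to-one peak matching; feasible for <= 8
# peaks per spectrum; maximizes the same objective as modified_cosine()
oracle_modified_cosine <- function(a, b, fragment_tol = 0.02,
                                   precursor_tol = 0.01) {
  ua <- sqrt(a$peaks[, "intensity"]); ub <- sqrt(b$peaks[, "intensity"])
  ua <- ua / sqrt(sum(ua^2)); ub <- ub / sqrt(sum(ub^2))
  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  delta <- b$precursor_mz - a$precursor_mz
  offsets <- if (abs(delta) > precursor_tol) c(0, delta) else 0
  pairs <- NULL
  for (off in offsets) {
    for (i in seq_along(mza)) {
      for (j in seq_along(mzb)) {
        if (abs(mza[i] + off - mzb[j]) <= fragment_tol) {
          pairs <- rbind(pairs, c(i, j))
        }
      }
    }
  }
  if (is.null(pairs)) return(0)
  pairs <- unique(pairs)
  best <- 0
  recurse <- function(k, used_a, used_b, acc) {
    if (acc > best) best <<- acc
    if (k > nrow(pairs)) return()
    recurse(k + 1L, used_a, used_b, acc)   # skip pair k
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      recurse(k + 1L, used_a, used_b, acc + ua[i] * ub[j])
    }
  }
  recurse(1L, logical(length(mza)), logical(length(mzb)), 0)
  best
}

# connected components by union-find over an edge data.frame
uf_components <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges$id_a[k]); rb <- find(edges$id_b[k])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  vapply(nodes, find, character(1))
}

# random spectrum pair with controlled overlap: some peaks shared
# directly, some shared at the precursor-difference offset, some unique
random_spectrum_pair <- function(n_max = 8L) {
  na <- sample(2:n_max, 1); nb <- sample(2:n_max, 1)
  prec_a <- runif(1, 300, 500)
  delta <- sample(c(0, runif(1, 2, 60)), 1)
  mza <- sort(runif(na, 100, prec_a - 5))
  n_shared <- sample(0:min(na, nb), 1)
  mzb <- numeric(0)
  if (n_shared > 0) {
    src <- sample(seq_len(na), n_shared)
    shift <- sample(c(0, delta), n_shared, replace = TRUE)
    mzb <- mza[src] + shift + rnorm(n_shared, 0, 0.004)
  }
  if (nb > n_shared) mzb <- c(mzb, runif(nb - n_shared, 100, prec_a + delta - 5))
  list(
    a = msms_spectrum("a", prec_a, 10, cbind(mza, runif(na, 0.1, 10))),
    b = msms_spectrum("b", prec_a + delta, 10, cbind(mzb, runif(nb, 0.1, 10)))
  )
}

# brute-force formula search by nested loops (CHO only), independent of
# the package's vectorized lattice enumeration
oracle_infer_cho <- function(delta_mass, tol_ppm, cmax, hmax, omax) {
  masses <- c(C = 12.0, H = 1.0078250319, O = 15.9949146221)
  out <- character(0); errs <- numeric(0)
  for (nc in 0:cmax) for (nh in 0:hmax) for (no in 0:omax) {
    m <- nc * masses["C"] + nh * masses["H"] + no * masses["O"]
    if (m == 0) next
    ppm <- (m - delta_mass) / delta_mass * 1e6
    if (abs(ppm) <= tol_ppm) {
      f <- paste0(if (nc) paste0("C", if (nc > 1) nc) else "",
                  if (nh) paste0("H", if (nh > 1) nh) else "",
                  if (no) paste0("O", if (no > 1) no) else "")
      out <- c(out, f); errs <- c(errs, abs(ppm))
    }
  }
  out[order(errs, out)]
}

# write a spectral-library MGF from a set of spectra plus names/formulas
make_library_mgf <- function(spectra, names, formulas, path) {
  for (i in seq_along(spectra)) {
    attr(spectra[[i]], "mgf_fields") <- list(NAME = names[i],
                                             FORMULA = formulas[i])
  }
  write_mgf(spectra, path)
}

# template spectrum printed in negative-mode triterpenoid work: an
# RAA-type side-chain acid with its core cleavage series
raa_like_spectrum <- function(feature_id = "RAA", precursor = 463.2854,
                              rt = 16.87) {
  msms_spectrum(
    feature_id, precursor, rt,
    cbind(c(419.296, 403.264, 301.217, 285.186, 261.186, 245.154, 229.123),
          c(1000, 900, 600, 550, 500, 400, 300)))
}
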