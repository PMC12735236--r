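#' Molecular-networking parameters
#'
#' Defaults follow the standard FBMN workflow settings for this kind of
#' Q-TOF data: parent mass tolerance 0.01 Da, fragment-ion tolerance
#' 0.02 Da, edges kept only above cosine 0.7 with more than four matching
#' peaks, mutual top-10 neighbour pruning, and molecular families capped
#' at 100 nodes.
#'
#' @param fragment_tol Fragment matching tolerance, Da.
#' @param precursor_tol Parent mass tolerance, Da.
#' @param cosine_min Edges must score strictly above this.
#' @param min_matched_peaks Minimum matched peak pairs per edge
#'   ("more than four" read as >= 5).
#' @param top_k Mutual top-K neighbour count.
#' @param max_family_size Maximum connected-component size.
#' @return A `network_params` list.
#' @export
network_params <- function(fragment_tol = 0.02, precursor_tol = 0.01,
                           cosine_min = 0.7, min_matched_peaks = 5L,
                           top_k = 10L, max_family_size = 100L) {
  stopifnot(fragment_tol > 0, precursor_tol > 0,
            cosine_min > 0, cosine_min <= 1,
            min_matched_peaks >= 1, top_k >= 1, max_family_size >= 1)
  structure(list(fragment_tol = fragment_tol, precursor_tol = precursor_tol,
                 cosine_min = cosine_min,
                 min_matched_peaks = as.integer(min_matched_peaks),
                 top_k = as.integer(top_k),
                 max_family_size = as.integer(max_family_size)),
            class = "network_params")
}

#' Build a feature-based molecular network
#'
#' All-pairs modified cosine over the spectra, then three deterministic
#' filters: (1) drop pairs at or below `cosine_min` or with fewer than
#' `min_matched_peaks` matched peaks; (2) keep an edge only if each node
#' ranks within the other's top `top_k` neighbours (by cosine descending,
#' id ascending); (3) while any connected component (molecular family)
#' exceeds `max_family_size`, delete the lowest-cosine edge inside an
#' oversized component (ties broken by the lexicographically smallest
#' `(id_a, id_b)` pair).
#'
#' @param spectra List of [msms_spectrum] objects with unique feature ids.
#' @param params A [network_params] object.
#' @return A `molecular_network`: `nodes` (feature ids), `edges`
#'   (data.frame `id_a`, `id_b`, `cosine`, `n_matched` with `id_a < id_b`),
#'   and the `params` used.
#' @export
build_network <- function(spectra, params = network_params()) {
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  if (anyDuplicated(ids)) stop("feature ids must be unique")
  n <- length(spectra)
  edges <- data.frame(id_a = character(0), id_b = character(0),
                      cosine = numeric(0), n_matched = integer(0),
                      stringsAsFactors = FALSE)
  if (n >= 2) {
    rows <- list()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (nrow(spectra[[i]]$peaks) == 0L || nrow(spectra[[j]]$peaks) == 0L) next
        mc <- modified_cosine(spectra[[i]], spectra[[j]],
                              fragment_tol = params$fragment_tol,
                              precursor_tol = params$precursor_tol)
        if (mc$score > params$cosine_min &&
            mc$n_matched >= params$min_matched_peaks) {
          ab <- sort(c(ids[i], ids[j]))
          rows[[length(rows) + 1L]] <- data.frame(
            id_a = ab[1], id_b = ab[2], cosine = mc$score,
            n_matched = mc$n_matched, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges <- .mutual_topk_filter(edges, params$top_k)
  edges <- .cap_family_size(edges, ids, params$max_family_size)
  structure(list(nodes = ids, edges = edges, params = params),
            class = "molecular_network")
}

# keep an edge iff each endpoint ranks <= K among the other's neighbours,
# neighbours ordered by cosine desc then id asc
.mutual_topk_filter <- function(edges, top_k) {
  if (!nrow(edges)) return(edges)
  rank_of <- function(node) {
    sel <- edges$id_a == node | edges$id_b == node
    other <- ifelse(edges$id_a[sel] == node, edges$id_b[sel], edges$id_a[sel])
    ord <- order(-edges$cosine[sel], other)
    r <- integer(length(ord))
    r[ord] <- seq_along(ord)
    stats::setNames(r, other)
  }
  ranks <- lapply(stats::setNames(nm = unique(c(edges$id_a, edges$id_b))), rank_of)
  keep <- vapply(seq_len(nrow(edges)), function(k) {
    a <- edges$id_a[k]; b <- edges$id_b[k]
    ranks[[a]][[b]] <= top_k && ranks[[b]][[a]] <= top_k
  }, logical(1))
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.components <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::components(g)$membership[nodes]
}

.cap_family_size <- function(edges, nodes, max_family_size) {
  repeat {
    if (!nrow(edges)) break
    memb <- .components(edges, nodes)
    sizes <- table(memb)
    big <- as.integer(names(sizes)[sizes > max_family_size])
    if (!length(big)) break
    in_big <- memb[edges$id_a] %in% big
    cand <- which(in_big)
    k <- cand[order(edges$cosine[cand], edges$id_a[cand],
                    edges$id_b[cand])][1]
    edges <- edges[-k, , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' @export
print.molecular_network <- function(x, ...) {
  st <- network_stats(x)
  cat("<molecular_network> ", st$n_nodes, " nodes, ", nrow(x$edges),
      " edges, ", st$n_singletons, " singletons\n", sep = "")
  invisible(x)
}

#' Summary statistics of a molecular network
#'
#' @param net A `molecular_network`.
#' @return List with `n_nodes`, `n_singletons` (degree-0 nodes), and
#'   `component_sizes`: a named integer vector mapping component size
#'   (>= 2) to the number of components of that size.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "molecular_network"))
  n_nodes <- length(net$nodes)
  if (!nrow(net$edges)) {
    return(list(n_nodes = n_nodes, n_singletons = n_nodes,
                component_sizes = stats::setNames(integer(0), character(0))))
  }
  memb <- .components(net$edges, net$nodes)
  sizes <- table(memb)
  nontrivial <- sizes[sizes >= 2]
  hist <- table(as.integer(nontrivial))
  list(n_nodes = n_nodes,
       n_singletons = sum(sizes == 1),
       component_sizes = stats::setNames(as.integer(hist), names(hist)))
}

#' Export a molecular network as GraphML
#'
#' Nodes carry feature metadata (m/z, retention time and, when a feature
#' table is supplied, per-sample intensity shares for pie-chart
#' rendering); edges carry the cosine score and matched-peak count.
#' Output element order is deterministic.
#'
#' @param net A `molecular_network`.
#' @param path Output path.
#' @param feature_table Optional [feature_table] providing node metadata.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, feature_table = NULL) {
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes))
  if (!is.null(feature_table)) {
    idx <- match(net$nodes, feature_table$features$feature_id)
    igraph::V(g)$mz <- feature_table$features$mz[idx]
    igraph::V(g)$rt <- feature_table$features$rt[idx]
    inten <- feature_table$intensities[idx, , drop = FALSE]
    totals <- rowSums(inten)
    totals[totals == 0] <- 1
    shares <- inten / totals
    for (s in feature_table$samples) {
      g <- igraph::set_vertex_attr(g, paste0("share_", s),
                                   value = round(shares[, s], 6))
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the network edge list as CSV
#'
#' @param net A `molecular_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(net, path) {
  df <- net$edges
  df$cosine <- sprintf("%.6f", df$cosine)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
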