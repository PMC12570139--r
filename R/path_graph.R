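# NMI-weighted residue contact graph and maximum-cumulative-NMI path tracing.
# Dijkstra maximization is obtained by minimizing a nonnegative edge cost
# transform of the NMI (default 1 - NMI); the reported path score is the sum
# of edge NMI values.

edge_cost <- function(w, transform) {
  eps <- 1e-12
  switch(transform,
         one_minus = 1 - w,
         inverse   = 1 / pmax(w, eps),
         neglog    = -log(pmax(w, eps)),
         stop("unknown cost transform: ", transform))
}

#' Build the NMI-weighted residue contact graph
#'
#' Nodes are residues; an undirected edge joins residues whose minimum
#' heavy-atom distance is within `contact_cutoff` (inclusive), weighted by
#' their NMI. Each edge also carries a nonnegative Dijkstra cost derived from
#' the weight (`1 - NMI` by default).
#'
#' @param nmi An `ap_nmi` matrix.
#' @param dist An `ap_distmat` covering (at least) the NMI residues.
#' @param contact_cutoff Contact distance cutoff in Angstrom (default 5).
#' @param transform Cost transform: `"one_minus"` (default), `"inverse"`, or
#'   `"neglog"`.
#' @return An [igraph::igraph] graph with vertex `name` = residue label and
#'   edge attributes `nmi` and `cost`; graph attributes record the cutoff and
#'   transform.
#' @export
build_graph <- function(nmi, dist, contact_cutoff = 5.0,
                        transform = c("one_minus", "inverse", "neglog")) {
  transform <- match.arg(transform)
  labels <- rownames(nmi)
  if (!all(labels %in% rownames(dist)))
    stop("distance matrix missing residues: ",
         paste(setdiff(labels, rownames(dist)), collapse = ", "))
  d <- dist[labels, labels]
  n <- length(labels)
  sel <- which(upper.tri(d) & d <= contact_cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0)
    stop("no residue contacts within ", contact_cutoff,
         " Angstrom; graph would be empty")
  w <- nmi[sel]
  g <- igraph::graph_from_data_frame(
    data.frame(from = labels[sel[, 1]], to = labels[sel[, 2]],
               nmi = w, cost = edge_cost(w, transform),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = labels, stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "contact_cutoff", contact_cutoff)
  igraph::set_graph_attr(g, "transform", transform)
}

#' Select spatially distant residue pairs
#'
#' All unordered residue pairs separated by at least `min_separation`
#' (inclusive), in deterministic ascending-index order. These are the
#' source/target pairs between which paths are traced.
#'
#' @param dist An `ap_distmat`.
#' @param min_separation Minimum separation in Angstrom (default 12).
#' @return Data frame with columns `from`, `to` (residue labels) and
#'   `distance`.
#' @export
select_distant_pairs <- function(dist, min_separation = 12.0) {
  sel <- which(upper.tri(dist) & dist >= min_separation, arr.ind = TRUE)
  sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
  out <- data.frame(from = rownames(dist)[sel[, 1]],
                    to = colnames(dist)[sel[, 2]],
                    distance = dist[sel],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0)
    warning("no residue pairs separated by >= ", min_separation,
            " Angstrom; no paths will be traced")
  out
}

path_from_vertices <- function(graph, vnames) {
  eids <- igraph::get_edge_ids(graph,
                               rbind(vnames[-length(vnames)], vnames[-1]))
  w <- igraph::E(graph)$nmi[eids]
  vidx <- match(vnames, igraph::V(graph)$name)
  if (vidx[1] > vidx[length(vidx)]) {  # canonical: lower endpoint first
    vnames <- rev(vnames); vidx <- rev(vidx)
  }
  structure(list(residues = vnames, score = sum(w),
                 key = paste(vidx, collapse = "-")),
            class = "ap_path")
}

#' Maximum-cumulative-NMI path between two residues
#'
#' Runs Dijkstra's algorithm on the edge costs (the minimized total cost under
#' the `1 - NMI` transform corresponds to maximizing cumulative NMI relative
#' to path length) and reports the path with its score, the sum of edge NMI
#' values. Returns `NULL` if the residues are disconnected.
#'
#' @param graph Graph from [build_graph()].
#' @param source,target Residue labels.
#' @return An `ap_path` (list: `residues`, `score`, `key`) or `NULL`.
#' @export
max_nmi_path <- function(graph, source, target) {
  if (identical(source, target)) stop("source and target must differ")
  sp <- suppressWarnings(
    igraph::shortest_paths(graph, from = source, to = target,
                           weights = igraph::E(graph)$cost,
                           output = "vpath")
  )
  v <- sp$vpath[[1]]
  if (length(v) == 0) return(NULL)
  path_from_vertices(graph, igraph::V(graph)$name[as.integer(v)])
}

#' Trace and rank paths for a set of residue pairs
#'
#' Computes the best (maximum cumulative NMI) path for every reachable pair
#' and retains the top `k` by score. Ties are broken lexicographically on the
#' canonical residue sequence so reruns are bit-identical.
#'
#' @param graph Graph from [build_graph()].
#' @param pairs Data frame from [select_distant_pairs()] (columns `from`,
#'   `to`).
#' @param k Number of paths to retain (default 500).
#' @return An `ap_pathset`: list with `paths` (list of `ap_path`, descending
#'   score), `table` (data frame: source, target, length, score), `k`,
#'   `n_candidates`, `n_unreachable`.
#' @export
trace_paths <- function(graph, pairs, k = 500) {
  if (nrow(pairs) == 0) stop("no residue pairs to trace")
  vnames <- igraph::V(graph)$name
  miss <- setdiff(unique(c(pairs$from, pairs$to)), vnames)
  pairs <- pairs[!(pairs$from %in% miss) & !(pairs$to %in% miss), ,
                 drop = FALSE]
  paths <- list()
  prov_from <- character(0); prov_to <- character(0)
  unreach <- 0L
  for (src in unique(pairs$from)) {
    targets <- pairs$to[pairs$from == src]
    sp <- suppressWarnings(
      igraph::shortest_paths(graph, from = src, to = targets,
                             weights = igraph::E(graph)$cost,
                             output = "vpath")
    )
    for (ti in seq_along(targets)) {
      v <- sp$vpath[[ti]]
      if (length(v) == 0) { unreach <- unreach + 1L; next }
      paths[[length(paths) + 1]] <-
        path_from_vertices(graph, vnames[as.integer(v)])
      prov_from <- c(prov_from, src)
      prov_to <- c(prov_to, targets[ti])
    }
  }
  if (length(paths) == 0)
    stop("no reachable residue pairs (", unreach, " pairs disconnected)")
  scores <- vapply(paths, `[[`, numeric(1), "score")
  keys <- vapply(paths, `[[`, character(1), "key")
  ord <- order(-scores, keys)
  keep <- ord[seq_len(min(k, length(ord)))]
  tab <- data.frame(
    source = prov_from[keep], target = prov_to[keep],
    length = vapply(paths[keep], function(p) length(p$residues), integer(1)),
    score = scores[keep], stringsAsFactors = FALSE
  )
  structure(list(paths = paths[keep], table = tab, k = k,
                 n_candidates = length(paths), n_unreachable = unreach),
            class = "ap_pathset")
}

#' Restrict pairs or paths to a residue set
#'
#' Implements ligand-contact-restricted tracking: in `"endpoint"` mode (for a
#' pair table) only source/target pairs with at least one endpoint in the
#' restriction set are kept; in `"contains"` mode (for a path set) paths are
#' retained if any residue lies in the set.
#'
#' @param x A pair data frame (endpoint mode) or `ap_pathset` (contains mode).
#' @param restriction Character vector of residue labels.
#' @param mode `"endpoint"` (default) or `"contains"`.
#' @param universe Residue labels of the topology, used to validate the
#'   restriction set (fatal if any restriction residue is absent).
#' @return Filtered object of the same type.
#' @export
filter_by_residues <- function(x, restriction,
                               mode = c("endpoint", "contains"),
                               universe = NULL) {
  mode <- match.arg(mode)
  if (length(restriction) == 0) stop("restriction set is empty")
  if (!is.null(universe)) {
    bad <- setdiff(restriction, universe)
    if (length(bad))
      stop("restriction residues absent from topology: ",
           paste(bad, collapse = ", "))
  }
  if (mode == "endpoint") {
    if (!is.data.frame(x)) stop("endpoint mode expects a pair data frame")
    x[x$from %in% restriction | x$to %in% restriction, , drop = FALSE]
  } else {
    if (!inherits(x, "ap_pathset")) stop("contains mode expects an ap_pathset")
    keep <- vapply(x$paths, function(p) any(p$residues %in% restriction),
                   logical(1))
    x$paths <- x$paths[keep]
    x$table <- x$table[keep, , drop = FALSE]
    x
  }
}

#' Motif occurrence within top-ranked paths
#'
#' For each named motif (a set of residues), counts how many top paths contain
#' each member residue — per replica and summed over replicas — and reports
#' the motif occurrence as the maximum frequency of any single member residue.
#'
#' @param path_sets One `ap_pathset` or a list of them (one per replica).
#' @param motifs Named list of residue-label vectors.
#' @param universe Optional topology residue labels for validation (fatal if a
#'   motif residue is absent).
#' @return An `ap_motifs`: data frame with columns `motif`, `occurrence`
#'   (summed over replicas), `top_residue`, plus per-replica occurrences as
#'   attribute `per_replica` and per-residue frequencies as attribute
#'   `residue_freq`.
#' @export
motif_occurrence <- function(path_sets, motifs, universe = NULL) {
  if (inherits(path_sets, "ap_pathset")) path_sets <- list(path_sets)
  if (length(path_sets) < 1) stop("need at least one path set")
  if (is.null(names(motifs)) || any(names(motifs) == ""))
    stop("motifs must be a named list")
  if (!is.null(universe)) {
    bad <- setdiff(unlist(motifs), universe)
    if (length(bad))
      stop("motif residues absent from topology: ",
           paste(bad, collapse = ", "))
  }
  freq_one <- function(ps, residues) {
    vapply(residues, function(r) {
      sum(vapply(ps$paths, function(p) r %in% p$residues, logical(1)))
    }, numeric(1))
  }
  per_rep <- matrix(0, length(motifs), length(path_sets),
                    dimnames = list(names(motifs),
                                    paste0("replica", seq_along(path_sets))))
  occ <- numeric(length(motifs)); top <- character(length(motifs))
  residue_freq <- vector("list", length(motifs))
  names(residue_freq) <- names(motifs)
  for (mi in seq_along(motifs)) {
    residues <- motifs[[mi]]
    fmat <- vapply(path_sets, freq_one, numeric(length(residues)),
                   residues = residues)
    fmat <- matrix(fmat, nrow = length(residues),
                   dimnames = list(residues, NULL))
    per_rep[mi, ] <- apply(fmat, 2, max)
    total <- rowSums(fmat)
    occ[mi] <- max(total)
    top[mi] <- residues[which.max(total)]
    residue_freq[[mi]] <- total
  }
  out <- data.frame(motif = names(motifs), occurrence = occ,
                    top_residue = top, stringsAsFactors = FALSE)
  structure(out, per_replica = per_rep, residue_freq = residue_freq,
            class = c("ap_motifs", "data.frame"))
}

#' @export
print.ap_pathset <- function(x, n = 5, ...) {
  cat("Path set:", length(x$paths), "paths (of", x$n_candidates,
      "candidate pairs,", x$n_unreachable, "unreachable), k =", x$k, "\n")
  if (length(x$paths)) {
    cat("Top paths by cumulative NMI:\n")
    print(utils::head(x$table, n), row.names = FALSE)
  }
  invisible(x)
}
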