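# Grouping top-ranked paths into distinct allosteric routes: a spatial
# overlap count between paths is normalized into a dissimilarity in [0, 1],
# fed to agglomerative clustering, and the cluster count chosen by silhouette.

#' Spatial overlap between two paths
#'
#' Counts residue pairs (r in p, s in q) whose minimum heavy-atom distance is
#' within `overlap_cutoff`. Identical paths overlap at least once per residue
#' (every residue is within 0 Angstrom of itself).
#'
#' @param p,q `ap_path` objects (or character vectors of residue labels).
#' @param dist An `ap_distmat` covering both paths' residues.
#' @param overlap_cutoff Distance cutoff in Angstrom (default 12).
#' @return Integer overlap count.
#' @export
path_overlap <- function(p, q, dist, overlap_cutoff = 12.0) {
  rp <- if (inherits(p, "ap_path")) p$residues else p
  rq <- if (inherits(q, "ap_path")) q$residues else q
  sum(dist[rp, rq, drop = FALSE] <= overlap_cutoff)
}

#' Path dissimilarity matrix
#'
#' Normalizes the pairwise overlap count into
#' `d(p, q) = 1 - overlap(p, q) / (|p| * |q|)`, clamped to `[0, 1]`, with zero
#' diagonal. The normalization bounds the dissimilarity and removes
#' path-length bias.
#'
#' @param paths An `ap_pathset` (or list of `ap_path`).
#' @param dist An `ap_distmat`.
#' @param overlap_cutoff Distance cutoff in Angstrom (default 12).
#' @return An `ap_pathdiss` symmetric matrix with attribute `overlap_cutoff`.
#' @export
path_dissimilarity <- function(paths, dist, overlap_cutoff = 12.0) {
  plist <- if (inherits(paths, "ap_pathset")) paths$paths else paths
  n <- length(plist)
  if (n < 2) stop("need at least 2 paths for a dissimilarity matrix")
  res <- lapply(plist, function(p) if (inherits(p, "ap_path")) p$residues else p)
  len <- lengths(res)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ov <- sum(dist[res[[i]], res[[j]], drop = FALSE] <= overlap_cutoff)
      d[i, j] <- d[j, i] <- clamp(1 - ov / (len[i] * len[j]), 0, 1)
    }
  }
  structure(d, overlap_cutoff = overlap_cutoff,
            class = c("ap_pathdiss", "matrix", "array"))
}

#' Cluster paths into distinct routes
#'
#' Agglomerative hierarchical clustering (average linkage by default) on the
#' precomputed path dissimilarity, cut at each candidate cluster count; the
#' count maximizing the mean silhouette width (computed on the same
#' dissimilarity via [cluster::silhouette()]) is selected. Ties prefer the
#' smallest count. With fewer than 3 paths, or all-identical paths, a single
#' cluster is returned with a warning.
#'
#' @param d An `ap_pathdiss` matrix.
#' @param k_range Integer vector of candidate cluster counts; default
#'   `2:min(10, n - 1)`.
#' @param linkage Linkage method for [stats::hclust()] (default `"average"`).
#' @return An `ap_clusters`: list with `labels` (per-path cluster id),
#'   `k_star`, `silhouette` (data frame k / mean silhouette width),
#'   `linkage`, `hclust`.
#' @export
cluster_paths <- function(d, k_range = NULL, linkage = "average") {
  n <- nrow(d)
  single <- function(msg) {
    warning(msg)
    structure(list(labels = rep(1L, n), k_star = 1L,
                   silhouette = data.frame(k = integer(0),
                                           silhouette = numeric(0)),
                   linkage = linkage, hclust = NULL),
              class = "ap_clusters")
  }
  if (n < 3) return(single("fewer than 3 paths; returning a single cluster"))
  if (all(d == 0))
    return(single("all paths identical; silhouette undefined, single cluster"))
  if (is.null(k_range)) k_range <- 2:min(10, n - 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range values must lie in [2, n_paths - 1]")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(lab, dmatrix = d)[, 3])
  }, numeric(1))
  k_star <- k_range[which.max(sil)]  # which.max: first (smallest k) on ties
  structure(list(labels = unname(stats::cutree(hc, k = k_star)),
                 k_star = k_star,
                 silhouette = data.frame(k = k_range, silhouette = sil),
                 linkage = linkage, hclust = hc),
            class = "ap_clusters")
}

#' Per-cluster residue-pair traversal counts
#'
#' For each cluster, counts how many member paths traverse each consecutive
#' residue pair (an unordered graph edge). These counts drive the
#' frequency-scaled radii of the exported path geometry.
#'
#' @param assignment An `ap_clusters` from [cluster_paths()].
#' @param paths The `ap_pathset` that was clustered (same order).
#' @return Data frame with columns `cluster`, `r1`, `r2`, `count`, sorted
#'   deterministically.
#' @export
cluster_summary <- function(assignment, paths) {
  plist <- if (inherits(paths, "ap_pathset")) paths$paths else paths
  stopifnot(length(assignment$labels) == length(plist))
  rows <- list()
  for (i in seq_along(plist)) {
    r <- plist[[i]]$residues
    if (length(r) < 2) next
    a <- r[-length(r)]; b <- r[-1]
    swap <- a > b  # canonical unordered pair (lexicographic)
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    rows[[i]] <- data.frame(cluster = assignment$labels[i], r1 = a, r2 = b,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = all[c("cluster", "r1", "r2")], FUN = sum)
  agg[order(agg$cluster, agg$r1, agg$r2), , drop = FALSE]
}

#' @export
print.ap_clusters <- function(x, ...) {
  cat("Path clustering: k* =", x$k_star, "(", x$linkage, "linkage )\n")
  if (nrow(x$silhouette)) {
    cat("Mean silhouette by k:\n")
    print(x$silhouette, row.names = FALSE)
  }
  cat("Cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}
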