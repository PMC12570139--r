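# Independent oracles used across test files. Each deliberately re-derives
# the quantity with a different algorithm than the implementation under test.

# Literal cell-by-cell summation of the MI definition.
mi_loop_oracle <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  s
}

# Exhaustive simple-path enumeration minimizing sum(1 - w) over edges.
# w: weight matrix with NA where no edge exists. Returns best path and cost.
enumerate_best_path <- function(w, s, t) {
  n <- nrow(w)
  best <- NULL; best_cost <- Inf
  rec <- function(path, cost) {
    v <- path[length(path)]
    if (cost >= best_cost - 1e-12 && v != t) return()
    if (v == t) {
      if (cost < best_cost - 1e-12) { best <<- path; best_cost <<- cost }
      return()
    }
    for (u in seq_len(n)) {
      if (!is.na(w[v, u]) && !(u %in% path)) rec(c(path, u), cost + 1 - w[v, u])
    }
  }
  rec(s, 0)
  list(path = best, cost = best_cost)
}

# Canonical orientation used by the implementation: lower endpoint first.
canonical_path <- function(idx) {
  if (is.null(idx)) return(NULL)
  if (idx[1] > idx[length(idx)]) rev(idx) else idx
}

# From-scratch mean silhouette width on a precomputed dissimilarity.
silhouette_oracle <- function(labels, d) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Minimal binary STL parser (little-endian): header, triangle count, facets.
read_stl_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  normals <- matrix(0, nt, 3); tris <- matrix(0, nt, 9)
  for (i in seq_len(nt)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    normals[i, ] <- vals[1:3]; tris[i, ] <- vals[4:12]
  }
  list(n = nt, normals = normals, tris = tris)
}

# Build an NMI-style matrix and a contact distance matrix realizing an
# arbitrary weighted graph, so build_graph() reproduces exactly that topology.
graph_fixture <- function(w) {
  n <- nrow(w)
  labels <- paste0("A:", seq_len(n))
  nmi <- ifelse(is.na(w), 0, w)
  diag(nmi) <- 1
  dimnames(nmi) <- list(labels, labels)
  d <- ifelse(is.na(w), 100, 4)
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  list(nmi = structure(nmi, bins = 36, class = c("ap_nmi", "matrix", "array")),
       dist = structure(d, frames = 1L,
                        class = c("ap_distmat", "matrix", "array")))
}
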