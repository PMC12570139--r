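# Bootstrap stability of the top-ranked path set: trajectory frames are
# resampled with replacement (the same frame index vector for every residue,
# preserving per-frame cross-residue coupling), the whole NMI -> graph ->
# top-k analysis is rerun per replicate, and the dispersion of the overlap
# with the original top-k set is summarized as a standard error.

#' Resample trajectory frames of a dihedral matrix
#'
#' Draws frame indices with replacement (same count as the original) and
#' applies the SAME index vector to every residue, so per-frame cross-residue
#' coupling is preserved. Fully reproducible from the seed.
#'
#' @param dihedrals An `ap_dihedrals` matrix.
#' @param seed Integer RNG seed.
#' @return An `ap_dihedrals` matrix with attribute `resample_idx`.
#' @export
resample_frames <- function(dihedrals, seed) {
  n <- nrow(dihedrals)
  if (n < 2) stop("need at least 2 frames to resample")
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  out <- new_dihedrals(dihedrals[idx, , drop = FALSE],
                       attr(dihedrals, "valid"))
  attr(out, "resample_idx") <- idx
  out
}

#' Bootstrap analysis of top-path stability
#'
#' Reruns the NMI/graph/top-k analysis on `B` frame-resampled replicates of
#' the dihedral time series (graph topology and distances are held fixed:
#' resampling frames does not move atoms, only the NMI edge weights change).
#' Each replicate's top-k path set is compared with the original by canonical
#' residue tuple; the per-replicate overlap counts `n_b` are summarized as
#' `SE = sd(n_b) / sqrt(B)`.
#'
#' @param dihedrals An `ap_dihedrals` matrix.
#' @param dist An `ap_distmat`.
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Integer seed controlling all resampling.
#' @param bins,contact_cutoff,min_separation,top_k,transform Analysis
#'   parameters, as in the main pipeline.
#' @param pairs Optional precomputed pair table (default:
#'   [select_distant_pairs()] on `dist`).
#' @param resample_fun Optional hook `function(dihedrals, b)` returning the
#'   replicate-`b` dihedral matrix; defaults to frame resampling. An identity
#'   hook reproduces the original analysis exactly (SE = 0).
#' @return An `ap_bootstrap`: list with `B`, `k` (size of the original top-k
#'   set), `n_b` (per-replicate overlap counts), `se`, `mean_overlap`
#'   (mean `n_b / k`), `seed`.
#' @export
bootstrap_paths <- function(dihedrals, dist, B = 500, seed = 0,
                            bins = 36, contact_cutoff = 5.0,
                            min_separation = 12.0, top_k = 500,
                            transform = "one_minus", pairs = NULL,
                            resample_fun = NULL) {
  if (B < 2) stop("B must be >= 2")
  if (is.null(pairs)) pairs <- select_distant_pairs(dist, min_separation)
  run_once <- function(dih) {
    nmi <- nmi_matrix(dih, bins = bins)
    g <- build_graph(nmi, dist, contact_cutoff, transform)
    ps <- trace_paths(g, pairs, k = top_k)
    vapply(ps$paths, `[[`, character(1), "key")
  }
  orig_keys <- run_once(dihedrals)
  k <- length(orig_keys)
  # derive per-replicate seeds up front so replicate order is immaterial
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, B))
  n_b <- integer(B)
  for (b in seq_len(B)) {
    dih_b <- if (is.null(resample_fun)) resample_frames(dihedrals, rep_seeds[b])
             else resample_fun(dihedrals, b)
    n_b[b] <- length(intersect(run_once(dih_b), orig_keys))
  }
  structure(list(B = B, k = k, n_b = n_b,
                 se = stats::sd(n_b) / sqrt(B),
                 mean_overlap = mean(n_b) / k, seed = seed),
            class = "ap_bootstrap")
}

#' Bootstrap standard error of top-path occurrence
#'
#' Sample standard deviation of the per-replicate overlap counts divided by
#' `sqrt(B)`.
#'
#' @param result An `ap_bootstrap`, or a numeric vector of overlap counts.
#' @param k Maximum possible overlap (top-k size); required when `result` is a
#'   plain vector, used to validate `0 <= n_b <= k`.
#' @return Standard error (>= 0).
#' @export
standard_error <- function(result, k = NULL) {
  n_b <- if (inherits(result, "ap_bootstrap")) result$n_b else result
  if (inherits(result, "ap_bootstrap")) k <- result$k
  if (!is.null(k) && any(n_b < 0 | n_b > k))
    stop("overlap counts must lie in [0, k]")
  stats::sd(n_b) / sqrt(length(n_b))
}

#' @export
print.ap_bootstrap <- function(x, ...) {
  cat("Bootstrap path stability: B =", x$B, ", k =", x$k, "\n")
  cat(sprintf("  mean overlap n_b/k = %.3f, SE = %.4f (seed %d)\n",
              x$mean_overlap, x$se, x$seed))
  invisible(x)
}
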