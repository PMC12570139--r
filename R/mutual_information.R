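# Histogram-based entropy, mutual information and normalized mutual
# information (NMI) between residue dihedral time series. All information
# quantities are in bits (log base 2). Histograms use equal-width bins on the
# fixed support [-180, 180) so that bin edges do not depend on the data.

bin_index <- function(x, bins) {
  w <- 360 / bins
  idx <- floor((x + 180) / w) + 1
  # guard against floating-point landing exactly on the upper edge
  idx[idx > bins] <- bins
  idx[idx < 1] <- 1L
  as.integer(idx)
}

#' 1D angular histogram
#'
#' Equal-width histogram of dihedral angles over the fixed support
#' `[-180, 180)` degrees. `NA` entries (undefined phi) are dropped.
#'
#' @param x Numeric vector of angles in degrees, within `[-180, 180)`.
#' @param bins Number of bins (>= 2). Default 36 (10 degree bins).
#' @return An `ap_hist1` list: `edges` (length `bins + 1`), `counts`, `p`.
#' @export
angle_hist1d <- function(x, bins = 36) {
  if (bins < 2) stop("bins must be >= 2")
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty angle series")
  if (any(x < -180 | x >= 180)) stop("angles must lie in [-180, 180)")
  counts <- tabulate(bin_index(x, bins), nbins = bins)
  structure(list(edges = seq(-180, 180, length.out = bins + 1),
                 counts = counts, p = counts / sum(counts)),
            class = "ap_hist1")
}

#' 2D joint angular histogram
#'
#' Joint histogram of two angle series on the shared support, used as the
#' contingency table for mutual information. Frames where either series is
#' `NA` are dropped pairwise.
#'
#' @param x,y Angle series in degrees.
#' @inheritParams angle_hist1d
#' @return An `ap_hist2` list: `counts` (bins x bins matrix), `p`.
#' @export
angle_hist2d <- function(x, y, bins = 36) {
  if (length(x) != length(y)) stop("series lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no jointly defined frames")
  if (any(x < -180 | x >= 180) || any(y < -180 | y >= 180))
    stop("angles must lie in [-180, 180)")
  bi <- bin_index(x, bins); bj <- bin_index(y, bins)
  counts <- matrix(tabulate(bi + bins * (bj - 1L), nbins = bins * bins),
                   bins, bins)
  structure(list(counts = counts, p = counts / sum(counts)),
            class = "ap_hist2")
}

#' Shannon entropy of a histogram, in bits
#'
#' `H = -sum p log2 p`, with zero-probability bins contributing 0.
#'
#' @param h An `ap_hist1`, or a numeric vector of probabilities/counts.
#' @return Entropy in bits (>= 0).
#' @export
shannon_entropy <- function(h) {
  p <- if (inherits(h, "ap_hist1")) h$p else h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a joint histogram, in bits
#'
#' `MI = sum_xy P(x,y) log2( P(x,y) / (P(x) P(y)) )`, with the marginals taken
#' from the joint table itself; cells with `P(x,y) = 0` contribute 0.
#'
#' @param joint An `ap_hist2`, or a counts/probability matrix.
#' @return Mutual information in bits (>= 0 up to rounding).
#' @export
mutual_information <- function(joint) {
  p <- if (inherits(joint, "ap_hist2")) joint$p else joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  pv <- p[nz]
  sum(pv * log2(pv / (px[nz[, 1]] * py[nz[, 2]])))
}

#' Normalized mutual information
#'
#' `NMI = MI / sqrt(H(X) H(Y))`, the mutual information normalized by the
#' geometric mean of the marginal entropies, clamped to `[0, 1]`. When either
#' entropy is zero (a motionless residue) the NMI is defined as 0: a constant
#' dihedral carries no communicable signal.
#'
#' @param mi Mutual information in bits.
#' @param hx,hy Marginal entropies in bits.
#' @return NMI in `[0, 1]`.
#' @export
normalized_mi <- function(mi, hx, hy) {
  if (hx <= 0 || hy <= 0) return(0)
  clamp(mi / sqrt(hx * hy), 0, 1)
}

#' Residue-residue NMI matrix from dihedral time series
#'
#' Evaluates the normalized mutual information between the phi series of every
#' unordered residue pair, using a common equal-width binning on
#' `[-180, 180)`. Residues with undefined phi are excluded (and recorded in
#' the `dropped` attribute). For each pair, frames where either series is
#' undefined are dropped pairwise and the marginal entropies are taken from
#' the joint table of the retained frames, so MI and its normalization always
#' refer to the same sample. The diagonal is 1 for residues with positive
#' entropy, 0 otherwise.
#'
#' @param dihedrals An `ap_dihedrals` matrix from [compute_phi()].
#' @param bins Number of histogram bins (default 36).
#' @return An `ap_nmi`: symmetric matrix with residue labels as dimnames and
#'   attributes `bins`, `entropy` (per-residue full-series entropy, bits) and
#'   `dropped` (labels of phi-undefined residues).
#' @export
nmi_matrix <- function(dihedrals, bins = 36) {
  valid <- attr(dihedrals, "valid")
  if (is.null(valid)) valid <- apply(dihedrals, 2, function(x) any(!is.na(x)))
  labels <- colnames(dihedrals)
  keep <- which(valid)
  if (length(keep) < 2)
    stop("need at least 2 residues with defined phi, got ", length(keep))
  m <- dihedrals[, keep, drop = FALSE]
  n <- ncol(m)
  # precompute bin indices (NA preserved)
  bidx <- matrix(NA_integer_, nrow(m), n)
  for (j in seq_len(n)) {
    x <- m[, j]
    ok <- !is.na(x)
    bidx[ok, j] <- bin_index(x[ok], bins)
  }
  ent <- vapply(seq_len(n), function(j) {
    shannon_entropy(tabulate(bidx[!is.na(bidx[, j]), j], nbins = bins))
  }, numeric(1))
  out <- matrix(0, n, n, dimnames = list(labels[keep], labels[keep]))
  diag(out) <- as.numeric(ent > 0)
  for (i in seq_len(n - 1)) {
    bi_all <- bidx[, i]
    for (j in (i + 1):n) {
      ok <- !is.na(bi_all) & !is.na(bidx[, j])
      bi <- bi_all[ok]; bj <- bidx[ok, j]
      if (length(bi) == 0) next
      joint <- matrix(tabulate(bi + bins * (bj - 1L), nbins = bins * bins),
                      bins, bins)
      p <- joint / sum(joint)
      hx <- shannon_entropy(rowSums(p))
      hy <- shannon_entropy(colSums(p))
      v <- normalized_mi(mutual_information(p), hx, hy)
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  structure(out, bins = bins, entropy = stats::setNames(ent, labels[keep]),
            dropped = labels[!valid],
            class = c("ap_nmi", "matrix", "array"))
}

#' Write / read an NMI matrix as CSV
#'
#' Plain CSV with residue labels as header and row names, for caching the
#' (expensive) NMI computation between runs.
#'
#' @param nmi An `ap_nmi` matrix.
#' @param path Output CSV path.
#' @export
write_nmi_csv <- function(nmi, path) {
  utils::write.csv(as.data.frame(unclass(nmi)), path)
  invisible(path)
}

#' @rdname write_nmi_csv
#' @export
read_nmi_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  structure(m, class = c("ap_nmi", "matrix", "array"))
}
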