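# End-to-end analysis: one call from topology + trajectory to ranked,
# clustered allosteric communication paths, with optional ligand-contact
# restriction, motif occurrence counting and bootstrap stability.

#' Allosteric communication path analysis of an MD trajectory
#'
#' Runs the full pipeline: per-residue phi dihedrals, residue-residue
#' normalized mutual information, NMI-weighted contact graph, maximum-
#' cumulative-NMI path tracing between spatially distant residue pairs,
#' top-k ranking, hierarchical clustering of the retained paths into distinct
#' routes (silhouette-selected cluster count), and optionally motif
#' occurrence counting and bootstrap stability of the top-k set.
#'
#' @param topology Path to a PDB file, or an `ap_structure`.
#' @param trajectory Path to a DCD file, or an `ap_trajectory`; `NULL` uses
#'   the reference coordinates as a single frame.
#' @param contact_cutoff Contact-graph distance cutoff, Angstrom (default 5).
#' @param min_separation Minimum source/target separation, Angstrom (default
#'   12).
#' @param top_k Number of paths retained (default 500).
#' @param bins Histogram bin count for the NMI estimator (default 36, i.e.
#'   10 degree bins).
#' @param overlap_cutoff Path-overlap distance cutoff for clustering,
#'   Angstrom (default 12).
#' @param transform Edge cost transform for Dijkstra (default
#'   `"one_minus"`).
#' @param restriction Optional residue labels (`"<chain>:<resno>"`) for
#'   ligand-contact-restricted tracking.
#' @param restriction_mode `"endpoint"` (restrict traced pairs; default) or
#'   `"contains"` (filter retained paths).
#' @param motifs Optional named list of residue-label vectors for occurrence
#'   counting.
#' @param bootstrap_B Bootstrap replicate count; 0 skips the bootstrap
#'   (default 0).
#' @param seed Integer seed for all randomness (default 0).
#' @param distance_frames Frame selection for the distance matrix:
#'   `"first"`, `"all"`, or indices.
#' @param cluster_k Optional fixed candidate cluster counts (default
#'   `2:min(10, n - 1)`).
#' @return An object of class `allopath` with components `structure`, `phi`,
#'   `nmi`, `dist`, `graph`, `pairs`, `paths`, `dissimilarity`, `clusters`,
#'   `summary`, `motifs`, `bootstrap`, `config`, `timings`.
#' @examples
#' s <- make_chain_structure(10)
#' sim <- make_coupled_trajectory(s, frames = 400, kappa = 0.9, seed = 1)
#' fit <- allopath(s, sim$trajectory, top_k = 20, bootstrap_B = 0)
#' print(fit)
#' @export
allopath <- function(topology, trajectory = NULL,
                     contact_cutoff = 5.0, min_separation = 12.0,
                     top_k = 500, bins = 36, overlap_cutoff = 12.0,
                     transform = "one_minus",
                     restriction = NULL,
                     restriction_mode = c("endpoint", "contains"),
                     motifs = NULL, bootstrap_B = 0, seed = 0,
                     distance_frames = "first", cluster_k = NULL) {
  restriction_mode <- match.arg(restriction_mode)
  stopifnot(contact_cutoff > 0, min_separation > 0, overlap_cutoff > 0,
            top_k >= 1, bins >= 2)
  t0 <- proc.time()[["elapsed"]]
  tick <- local({
    last <- t0
    function() {
      now <- proc.time()[["elapsed"]]
      dt <- now - last; last <<- now; dt
    }
  })
  timings <- c()

  s <- if (inherits(topology, "ap_structure")) topology
       else read_topology(topology)
  traj <- if (is.null(trajectory) || inherits(trajectory, "ap_trajectory"))
    trajectory else read_trajectory(s, trajectory)
  timings["io"] <- tick()

  if (!is.null(restriction)) {
    bad <- setdiff(restriction, s$residues$label)
    if (length(bad))
      stop("restriction residues absent from topology: ",
           paste(bad, collapse = ", "))
  }

  phi <- compute_phi(s, traj)
  dist <- residue_min_distances(s, traj, frames = distance_frames)
  timings["geometry"] <- tick()

  nmi <- nmi_matrix(phi, bins = bins)
  timings["nmi"] <- tick()

  g <- build_graph(nmi, dist, contact_cutoff, transform)
  pairs <- select_distant_pairs(dist, min_separation)
  pairs <- pairs[pairs$from %in% rownames(nmi) & pairs$to %in% rownames(nmi),
                 , drop = FALSE]
  if (!is.null(restriction) && restriction_mode == "endpoint")
    pairs <- filter_by_residues(pairs, restriction, "endpoint",
                                universe = s$residues$label)
  paths <- trace_paths(g, pairs, k = top_k)
  if (!is.null(restriction) && restriction_mode == "contains")
    paths <- filter_by_residues(paths, restriction, "contains",
                                universe = s$residues$label)
  timings["paths"] <- tick()

  if (length(paths$paths) >= 3) {
    diss <- path_dissimilarity(paths, dist, overlap_cutoff)
    clusters <- cluster_paths(diss, k_range = cluster_k)
  } else {
    diss <- NULL
    clusters <- base::structure(
      list(labels = rep(1L, length(paths$paths)), k_star = 1L,
           silhouette = data.frame(k = integer(0), silhouette = numeric(0)),
           linkage = "average", hclust = NULL),
      class = "ap_clusters")
  }
  summ <- cluster_summary(clusters, paths)
  timings["clustering"] <- tick()

  motif_report <- if (!is.null(motifs))
    motif_occurrence(paths, motifs, universe = s$residues$label) else NULL

  boot <- NULL
  if (bootstrap_B > 0) {
    boot <- bootstrap_paths(phi, dist, B = bootstrap_B, seed = seed,
                            bins = bins, contact_cutoff = contact_cutoff,
                            min_separation = min_separation, top_k = top_k,
                            transform = transform, pairs = pairs)
    timings["bootstrap"] <- tick()
  }

  config <- list(contact_cutoff = contact_cutoff,
                 min_separation = min_separation, top_k = top_k,
                 bins = bins, overlap_cutoff = overlap_cutoff,
                 transform = transform, restriction = restriction,
                 restriction_mode = restriction_mode,
                 bootstrap_B = bootstrap_B, seed = seed,
                 distance_frames = as.character(distance_frames)[1])
  base::structure(
    list(structure = s, phi = phi, nmi = nmi, dist = dist, graph = g,
         pairs = pairs, paths = paths, dissimilarity = diss,
         clusters = clusters, summary = summ, motifs = motif_report,
         bootstrap = boot, config = config, timings = timings),
    class = "allopath")
}

#' @export
print.allopath <- function(x, ...) {
  cat("Allosteric communication path analysis\n")
  cat("  system:", nrow(x$structure$residues), "residues,",
      if (is.null(x$phi)) 1 else nrow(x$phi), "frames\n")
  cat("  NMI:", nrow(x$nmi), "residues,", attr(x$nmi, "bins"), "bins\n")
  cat("  graph:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges (contact cutoff",
      x$config$contact_cutoff, "A)\n")
  cat("  paths:", length(x$paths$paths), "retained of",
      x$paths$n_candidates, "candidates (top", x$config$top_k, ")\n")
  cat("  clusters: k* =", x$clusters$k_star, "\n")
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap: B = %d, SE = %.4f, mean overlap = %.3f\n",
                x$bootstrap$B, x$bootstrap$se, x$bootstrap$mean_overlap))
  invisible(x)
}

#' @export
summary.allopath <- function(object, n = 10, ...) {
  print(object)
  cat("\nTop paths:\n")
  print(utils::head(object$paths$table, n), row.names = FALSE)
  if (nrow(object$clusters$silhouette)) {
    cat("\nSilhouette by candidate cluster count:\n")
    print(object$clusters$silhouette, row.names = FALSE)
  }
  if (!is.null(object$motifs)) {
    cat("\nMotif occurrence:\n")
    print(as.data.frame(object$motifs), row.names = FALSE)
  }
  invisible(object)
}

#' Diagnostic plots for an allopath fit
#'
#' Draws the residue-residue NMI heatmap and, when available, the silhouette
#' profile over candidate cluster counts.
#'
#' @param x An `allopath` object.
#' @param which `"nmi"`, `"silhouette"`, or both (default).
#' @param ... Ignored.
#' @export
plot.allopath <- function(x, which = c("nmi", "silhouette"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("silhouette" %in% which && nrow(x$clusters$silhouette) == 0)
    which <- setdiff(which, "silhouette")
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if ("nmi" %in% which) {
    m <- unclass(x$nmi)
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "residue", ylab = "residue",
                    main = "dihedral NMI")
  }
  if ("silhouette" %in% which) {
    s <- x$clusters$silhouette
    graphics::plot(s$k, s$silhouette, type = "b", pch = 19,
                   xlab = "clusters k", ylab = "mean silhouette width",
                   main = "cluster count selection")
    graphics::abline(v = x$clusters$k_star, lty = 2)
  }
  invisible(x)
}

#' Write all serialized outputs of an analysis
#'
#' Writes, into `dir`: `paths.json` and `paths.tsv` (ranked path set),
#' `clusters.json` (cluster payload), `nmi.csv`, a PyMOL-style viewer script
#' `paths.pml`, a binary STL `paths.stl`, `bootstrap.json` +
#' `bootstrap_counts.csv` (when a bootstrap was run), `motifs.json` (when
#' motifs were counted), the echoed configuration `run.json`, and a `run.log`
#' with timings. All JSON outputs are byte-deterministic for a fixed config
#' and seed.
#'
#' @param fit An `allopath` object.
#' @param dir Output directory (created if needed).
#' @param stl Write the STL mesh (default TRUE).
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(fit, dir, stl = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  written <- character(0)
  write_pathset_json(fit$paths, fp("paths.json"))
  write_pathset_tsv(fit$paths, fp("paths.tsv"))
  write_nmi_csv(fit$nmi, fp("nmi.csv"))
  write_cluster_json(fit$clusters, fit$paths, fit$summary,
                     fp("clusters.json"))
  splines <- make_splines(fit$clusters, fit$summary, fit$paths,
                          fit$structure)
  write_viewer_script(splines, fp("paths.pml"))
  written <- c(written, fp(c("paths.json", "paths.tsv", "nmi.csv",
                             "clusters.json", "paths.pml")))
  if (stl) {
    write_stl(splines, fp("paths.stl"))
    written <- c(written, fp("paths.stl"))
  }
  if (!is.null(fit$bootstrap)) {
    b <- fit$bootstrap
    jsonlite::write_json(list(B = b$B, k = b$k, se = b$se,
                              mean_overlap = b$mean_overlap, seed = b$seed),
                         fp("bootstrap.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(replicate = seq_along(b$n_b),
                                overlap = b$n_b),
                     fp("bootstrap_counts.csv"), row.names = FALSE)
    written <- c(written, fp(c("bootstrap.json", "bootstrap_counts.csv")))
  }
  if (!is.null(fit$motifs)) {
    jsonlite::write_json(
      list(occurrence = as.data.frame(fit$motifs),
           per_replica = as.data.frame(attr(fit$motifs, "per_replica"))),
      fp("motifs.json"), auto_unbox = TRUE, digits = NA)
    written <- c(written, fp("motifs.json"))
  }
  jsonlite::write_json(fit$config, fp("run.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  log_lines <- c(
    paste("allopath", as.character(utils::packageVersion("allopath"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("date:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("seed:", fit$config$seed),
    sprintf("timing %s: %.2f s", names(fit$timings), fit$timings))
  writeLines(log_lines, fp("run.log"))
  invisible(c(written, fp(c("run.json", "run.log"))))
}

#' Serialize a path set as JSON / TSV
#'
#' JSON schema: `{"k", "paths": [{"source", "target", "residues", "score"}]}`;
#' the TSV has one path per row with residues dash-joined.
#'
#' @param paths An `ap_pathset`.
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
write_pathset_json <- function(paths, out) {
  payload <- list(
    k = paths$k,
    n_candidates = paths$n_candidates,
    n_unreachable = paths$n_unreachable,
    paths = lapply(seq_along(paths$paths), function(i) {
      p <- paths$paths[[i]]
      list(source = paths$table$source[i], target = paths$table$target[i],
           residues = p$residues, score = p$score)
    }))
  jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @rdname write_pathset_json
#' @export
write_pathset_tsv <- function(paths, out) {
  df <- paths$table
  df$residues <- vapply(paths$paths, function(p)
    paste(p$residues, collapse = "-"), character(1))
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
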