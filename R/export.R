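# Viewer-ready geometry: clustered paths become Catmull-Rom splines anchored
# to backbone C-alpha atoms, with per-segment radii scaled linearly by the
# path frequency of each residue-pair connection within its cluster. Writers:
# PyMOL-style CGO script, JSON payload, binary STL tube meshes.

# Interpolating Catmull-Rom spline through control points (m x 3), sampled at
# n_per_seg points per control segment plus the final endpoint. Endpoints are
# clamped by duplicating the terminal control points. A 2-point control set
# degenerates to a straight line.
catmull_rom <- function(control, n_per_seg = 10) {
  m <- nrow(control)
  stopifnot(m >= 2)
  ts <- seq(0, 1, length.out = n_per_seg + 1)[-(n_per_seg + 1)]
  ext <- rbind(control[1, ], control, control[m, ])
  pts <- list()
  for (j in seq_len(m - 1)) {
    p0 <- ext[j, ]; p1 <- ext[j + 1, ]; p2 <- ext[j + 2, ]; p3 <- ext[j + 3, ]
    a <- 2 * p1
    b <- p2 - p0
    cc <- 2 * p0 - 5 * p1 + 4 * p2 - p3
    dd <- -p0 + 3 * p1 - 3 * p2 + p3
    pts[[j]] <- 0.5 * (outer(rep(1, length(ts)), a) + outer(ts, b) +
                       outer(ts^2, cc) + outer(ts^3, dd))
  }
  rbind(do.call(rbind, pts), control[m, ])
}

radius_from_count <- function(count, max_count, r_min = 0.1, r_max = 0.6) {
  if (max_count <= 1) return(rep(r_min, length(count)))
  r_min + (r_max - r_min) * (count - 1) / (max_count - 1)
}

#' Build path splines anchored to C-alpha atoms
#'
#' Converts each clustered path into an interpolating Catmull-Rom spline
#' through its residues' C-alpha coordinates at the chosen frame, with one
#' radius per control segment scaled linearly between `r_min` and `r_max` by
#' that connection's traversal count within its cluster (all-equal counts map
#' to `r_min`).
#'
#' @param assignment An `ap_clusters`.
#' @param summary Data frame from [cluster_summary()].
#' @param paths The clustered `ap_pathset`.
#' @param structure An `ap_structure` (every path residue must have a CA
#'   atom).
#' @param trajectory Optional `ap_trajectory`; coordinates are taken from
#'   `frame` (default: reference coordinates / first frame).
#' @param frame Frame index for anchoring (default 1).
#' @param n_per_seg Sampled points per control segment (default 10).
#' @param r_min,r_max Radius range in Angstrom (defaults 0.1, 0.6).
#' @return List of `ap_spline` objects: `control` (m x 3), `points` (sampled
#'   polyline), `seg_radius` (per sampled segment), `cluster`, `residues`,
#'   `score`.
#' @export
make_splines <- function(assignment, summary, paths, structure,
                         trajectory = NULL, frame = 1, n_per_seg = 10,
                         r_min = 0.1, r_max = 0.6) {
  plist <- if (inherits(paths, "ap_pathset")) paths$paths else paths
  at <- structure$atoms
  ca_of <- function(label) {
    ri <- match(label, structure$residues$label)
    w <- which(at$res_idx == ri & at$elety == "CA")
    if (length(w) == 0) stop("missing CA atom for residue ", label)
    w[1]
  }
  coord <- function(i) {
    if (is.null(trajectory)) structure$xyz_ref[i, ]
    else trajectory$xyz[frame, (3 * i - 2):(3 * i)]
  }
  max_count <- stats::aggregate(count ~ cluster, data = summary, FUN = max)
  out <- vector("list", length(plist))
  for (pi in seq_along(plist)) {
    p <- plist[[pi]]
    cl <- assignment$labels[pi]
    ctrl <- t(vapply(p$residues, function(r) coord(ca_of(r)), numeric(3)))
    a <- p$residues[-length(p$residues)]; b <- p$residues[-1]
    swap <- a > b; tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    ssub <- summary[summary$cluster == cl, , drop = FALSE]
    counts <- vapply(seq_along(a), function(e) {
      w <- which(ssub$r1 == a[e] & ssub$r2 == b[e])
      if (length(w)) ssub$count[w[1]] else 1L
    }, numeric(1))
    mc <- max_count$count[max_count$cluster == cl]
    ctrl_rad <- radius_from_count(counts, if (length(mc)) mc else 1,
                                  r_min, r_max)
    pts <- catmull_rom(ctrl, n_per_seg)
    seg_radius <- rep(ctrl_rad, each = n_per_seg)
    out[[pi]] <- base::structure(
      list(control = ctrl, points = pts, seg_radius = seg_radius,
           cluster = cl, residues = p$residues, score = p$score),
      class = "ap_spline")
  }
  out
}

cluster_palette <- function(n) {
  base <- c("0.122,0.467,0.706", "1.000,0.498,0.055", "0.173,0.627,0.173",
            "0.839,0.153,0.157", "0.580,0.404,0.741", "0.549,0.337,0.294",
            "0.890,0.467,0.761", "0.498,0.498,0.498", "0.737,0.741,0.133",
            "0.090,0.745,0.812")
  base[((seq_len(n) - 1) %% length(base)) + 1]
}

#' Write a PyMOL-style viewer script
#'
#' Emits a deterministic text script that draws every spline as a chain of
#' CGO cylinders, grouped and colored per cluster from a fixed palette.
#'
#' @param splines List of `ap_spline` from [make_splines()].
#' @param out Output script path (conventionally `.pml`).
#' @return `out`, invisibly.
#' @export
write_viewer_script <- function(splines, out) {
  lines <- c("# allopath cluster path geometry",
             "from pymol.cgo import CYLINDER",
             "from pymol import cmd")
  if (length(splines)) {
    clusters <- sort(unique(vapply(splines, `[[`, numeric(1), "cluster")))
    pal <- cluster_palette(length(clusters))
    for (ci in seq_along(clusters)) {
      cl <- clusters[ci]
      members <- which(vapply(splines, `[[`, numeric(1), "cluster") == cl)
      for (mi in seq_along(members)) {
        sp <- splines[[members[mi]]]
        obj <- sprintf("cluster%02d_path%03d", cl, mi)
        segs <- character(nrow(sp$points) - 1)
        for (s in seq_len(nrow(sp$points) - 1)) {
          p1 <- sp$points[s, ]; p2 <- sp$points[s + 1, ]
          segs[s] <- sprintf(
            "CYLINDER,%.3f,%.3f,%.3f,%.3f,%.3f,%.3f,%.3f,%s,%s",
            p1[1], p1[2], p1[3], p2[1], p2[2], p2[3],
            sp$seg_radius[s], pal[ci], pal[ci])
        }
        lines <- c(lines,
                   sprintf("obj_%s = [ %s ]", obj, paste(segs, collapse = ", ")),
                   sprintf("cmd.load_cgo(obj_%s, '%s')", obj, obj))
      }
    }
  }
  writeLines(lines, out)
  invisible(out)
}

#' Write the cluster/path JSON payload
#'
#' Serializes clusters, member paths and per-connection counts/radii in a
#' stable schema:
#' `{"clusters": [{"id", "paths": [{"residues", "score"}],`
#' `"edges": [{"r1", "r2", "count", "radius"}]}]}`.
#' Round-trips losslessly through [jsonlite::fromJSON()].
#'
#' @param assignment An `ap_clusters`, or `NULL` for an empty payload.
#' @param paths The clustered `ap_pathset` (ignored when `assignment` is
#'   `NULL`).
#' @param summary Data frame from [cluster_summary()].
#' @param out Output JSON path.
#' @param r_min,r_max Radius range used for the reported radii.
#' @return `out`, invisibly.
#' @export
write_cluster_json <- function(assignment, paths, summary, out,
                               r_min = 0.1, r_max = 0.6) {
  payload <- list(clusters = list())
  if (!is.null(assignment)) {
    plist <- if (inherits(paths, "ap_pathset")) paths$paths else paths
    for (cl in sort(unique(assignment$labels))) {
      members <- which(assignment$labels == cl)
      ssub <- summary[summary$cluster == cl, , drop = FALSE]
      mc <- if (nrow(ssub)) max(ssub$count) else 1
      payload$clusters[[length(payload$clusters) + 1]] <- list(
        id = cl,
        paths = lapply(members, function(i)
          list(residues = plist[[i]]$residues, score = plist[[i]]$score)),
        edges = lapply(seq_len(nrow(ssub)), function(e)
          list(r1 = ssub$r1[e], r2 = ssub$r2[e], count = ssub$count[e],
               radius = radius_from_count(ssub$count[e], mc, r_min, r_max)))
      )
    }
  }
  jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# Closed tube mesh around a polyline: returns ntri x 9 matrix of triangle
# vertex coordinates. `sides`-gon cross-section; rings oriented by normal
# propagation along the polyline; flat fan caps. Triangle count for an open
# tube with s segments: 2*s*sides + 2*(sides - 2).
tube_mesh <- function(points, radii, sides = 8) {
  n <- nrow(points)
  stopifnot(n >= 2, length(radii) == n - 1, sides >= 3)
  tangents <- matrix(0, n, 3)
  tangents[1, ] <- points[2, ] - points[1, ]
  tangents[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2)
    tangents[2:(n - 1), ] <- points[3:n, , drop = FALSE] -
      points[1:(n - 2), , drop = FALSE]
  tangents <- tangents / pmax(row_norm(tangents), 1e-12)
  # initial normal: any direction not parallel to the first tangent
  t1 <- tangents[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * t1) * t1
  u <- u / sqrt(sum(u^2))
  ang <- 2 * pi * (seq_len(sides) - 1) / sides
  rings <- vector("list", n)
  for (i in seq_len(n)) {
    ti <- tangents[i, ]
    u <- u - sum(u * ti) * ti         # parallel transport of the frame
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) {                  # degenerate turn: rebuild frame
      ref <- if (abs(ti[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * ti) * ti
      nu <- sqrt(sum(u^2))
    }
    u <- u / nu
    v <- c(ti[2] * u[3] - ti[3] * u[2],
           ti[3] * u[1] - ti[1] * u[3],
           ti[1] * u[2] - ti[2] * u[1])
    r <- radii[min(i, n - 1)]
    rings[[i]] <- points[rep(i, sides), , drop = FALSE] +
      r * (outer(cos(ang), u) + outer(sin(ang), v))
  }
  tri <- list()
  nxt <- c(seq_len(sides)[-1], 1L)
  for (s in seq_len(n - 1)) {
    a <- rings[[s]]; b <- rings[[s + 1]]
    for (j in seq_len(sides)) {
      k <- nxt[j]
      tri[[length(tri) + 1]] <- c(a[j, ], a[k, ], b[j, ])
      tri[[length(tri) + 1]] <- c(a[k, ], b[k, ], b[j, ])
    }
  }
  for (ring in list(rings[[1]], rings[[n]])) {
    for (j in 2:(sides - 1)) {
      tri[[length(tri) + 1]] <- c(ring[1, ], ring[j, ], ring[j + 1, ])
    }
  }
  do.call(rbind, tri)
}

#' Write path splines as a binary STL mesh
#'
#' Each spline becomes a closed tube (default octagonal cross-section) with
#' per-segment radii; all tubes are concatenated into one binary STL file with
#' unit facet normals. An empty spline list yields a valid zero-triangle STL.
#'
#' @param splines List of `ap_spline`.
#' @param out Output STL path.
#' @param sides Cross-section side count (default 8).
#' @return `out`, invisibly.
#' @export
write_stl <- function(splines, out, sides = 8) {
  tris <- lapply(splines, function(sp)
    tube_mesh(sp$points, sp$seg_radius, sides))
  tris <- if (length(tris)) do.call(rbind, tris) else matrix(0, 0, 9)
  con <- file(out, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(tris)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(tris))) {
    v1 <- tris[i, 1:3]; v2 <- tris[i, 4:6]; v3 <- tris[i, 7:9]
    nrm <- c((v2[2] - v1[2]) * (v3[3] - v1[3]) - (v2[3] - v1[3]) * (v3[2] - v1[2]),
             (v2[3] - v1[3]) * (v3[1] - v1[1]) - (v2[1] - v1[1]) * (v3[3] - v1[3]),
             (v2[1] - v1[1]) * (v3[2] - v1[2]) - (v2[2] - v1[2]) * (v3[1] - v1[1]))
    nn <- sqrt(sum(nrm^2))
    nrm <- if (nn > 1e-12) nrm / nn else c(0, 0, 1)
    writeBin(as.numeric(c(nrm, v1, v2, v3)), con, size = 4,
             endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(out)
}
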