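# Contact graph construction, Dijkstra path tracing, ranking, restriction
# and motif occurrence.

test_that("contact cutoff is inclusive and edges match a brute-force filter", {
  set.seed(10)
  n <- 6
  labels <- paste0("A:", 1:n)
  d <- matrix(runif(n * n, 3, 8), n, n); d <- (d + t(d)) / 2; diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 4.9
  d[1, 3] <- d[3, 1] <- 5.1
  d[1, 4] <- d[4, 1] <- 5.0
  dimnames(d) <- list(labels, labels)
  nmi <- matrix(runif(n * n, 0.1, 0.9), n, n); nmi <- (nmi + t(nmi)) / 2
  diag(nmi) <- 1; dimnames(nmi) <- list(labels, labels)
  g <- build_graph(structure(nmi, class = c("ap_nmi", "matrix", "array")),
                   structure(d, class = c("ap_distmat", "matrix", "array")),
                   contact_cutoff = 5)
  am <- igraph::as_adjacency_matrix(g, sparse = FALSE)[labels, labels]
  expect_equal(am[1, 2], 1)  # 4.9 within
  expect_equal(am[1, 3], 0)  # 5.1 outside
  expect_equal(am[1, 4], 1)  # boundary inclusive
  ref <- (d <= 5) & upper.tri(d)
  expect_equal(igraph::ecount(g), sum(ref))
  for (e in seq_len(igraph::ecount(g))) {
    ends <- igraph::ends(g, e)
    expect_lte(d[ends[1], ends[2]], 5)
    expect_equal(igraph::E(g)$nmi[e], nmi[ends[1], ends[2]])
  }
})

test_that("a chain with only sequence-neighbor contacts yields a line graph", {
  s <- make_chain_structure(8)
  d <- residue_min_distances(s)
  set.seed(11)
  m <- matrix(runif(8 * 300, -180, 180), 300, 8,
              dimnames = list(NULL, s$residues$label))
  nmi <- nmi_matrix(allopath:::new_dihedrals(m), bins = 12)
  g <- build_graph(nmi, d)
  expect_equal(igraph::ecount(g), 7)
  degs <- igraph::degree(g)
  expect_equal(sort(unname(degs)), c(1, 1, rep(2, 6)))
})

test_that("distant-pair selection applies the inclusive 12 A threshold", {
  labels <- c("A:1", "A:2", "A:3")
  d <- matrix(c(0, 15, 10, 15, 0, 12, 10, 12, 0), 3, 3,
              dimnames = list(labels, labels))
  pairs <- select_distant_pairs(
    structure(d, class = c("ap_distmat", "matrix", "array")), 12)
  expect_equal(pairs$from, c("A:1", "A:2"))
  expect_equal(pairs$to, c("A:2", "A:3"))  # 15 and 12 in, 10 out
  expect_warning(
    empty <- select_distant_pairs(
      structure(diag(0, 3), class = c("ap_distmat", "matrix", "array")), 12),
    "no residue pairs")
  expect_equal(nrow(empty), 0)
})

test_that("chain geometry: sequence gap >= 4 is distant, small gaps are not", {
  s <- make_chain_structure(10)
  d <- residue_min_distances(s)
  pairs <- select_distant_pairs(d, 12)
  key <- paste(pairs$from, pairs$to)
  expect_true("A:1 A:5" %in% key)
  expect_false("A:1 A:3" %in% key)
  expect_true(all(abs(
    as.integer(sub("A:", "", pairs$to)) -
      as.integer(sub("A:", "", pairs$from))) >= 4))
})

test_that("the worked 4-node example picks the higher-NMI route", {
  w <- matrix(NA_real_, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9   # A-B
  w[2, 4] <- w[4, 2] <- 0.9   # B-D
  w[1, 3] <- w[3, 1] <- 0.8   # A-C
  w[3, 4] <- w[4, 3] <- 0.8   # C-D
  fx <- graph_fixture(w)
  g <- build_graph(fx$nmi, fx$dist, contact_cutoff = 5)
  p <- max_nmi_path(g, "A:1", "A:4")
  expect_equal(p$residues, c("A:1", "A:2", "A:4"))
  expect_equal(p$score, 1.8)
  oracle <- enumerate_best_path(w, 1, 4)
  expect_equal(p$residues, paste0("A:", canonical_path(oracle$path)))
  # single-edge query
  expect_equal(max_nmi_path(g, "A:1", "A:2")$score, 0.9)
  # disconnected components return NULL
  w2 <- matrix(NA_real_, 4, 4); w2[1, 2] <- w2[2, 1] <- 0.5
  w2[3, 4] <- w2[4, 3] <- 0.5
  fx2 <- graph_fixture(w2)
  g2 <- build_graph(fx2$nmi, fx2$dist)
  expect_null(max_nmi_path(g2, "A:1", "A:3"))
  expect_error(max_nmi_path(g, "A:1", "A:1"), "differ")
})

test_that("Dijkstra under the 1-NMI transform is optimal on random graphs", {
  set.seed(12)
  n_agree <- 0
  for (r in 1:200) {
    n <- sample(4:10, 1)
    w <- matrix(NA_real_, n, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < 0.45) w[i, j] <- w[j, i] <- runif(1, 0.05, 0.95)
      }
    }
    if (all(is.na(w))) next
    fx <- graph_fixture(w)
    g <- build_graph(fx$nmi, fx$dist)
    st <- sample(n, 2)
    have_both <- all(paste0("A:", st) %in% igraph::V(g)$name)
    oracle <- enumerate_best_path(w, st[1], st[2])
    p <- if (have_both) max_nmi_path(g, paste0("A:", st[1]),
                                     paste0("A:", st[2])) else NULL
    if (is.null(p)) {
      expect_true(is.null(oracle$path) || !have_both)
    } else {
      expect_equal(p$residues, paste0("A:", canonical_path(oracle$path)))
      expect_equal(sum(1 - igraph::E(g, path = p$residues)$nmi),
                   oracle$cost, tolerance = 1e-9)
      n_agree <- n_agree + 1
    }
  }
  expect_gt(n_agree, 100)  # most random graphs connect the sampled pair
})

test_that("trace ranking is deterministic, capped at k, canonical on ties", {
  w <- matrix(NA_real_, 6, 6)
  for (i in 1:5) w[i, i + 1] <- w[i + 1, i] <- 0.5
  fx <- graph_fixture(w)
  g <- build_graph(fx$nmi, fx$dist)
  pairs <- data.frame(from = c("A:1", "A:2", "A:1"),
                      to = c("A:5", "A:6", "A:6"),
                      stringsAsFactors = FALSE)
  ps <- trace_paths(g, pairs, k = 500)
  expect_equal(length(ps$paths), 3)   # k larger than supply keeps all
  expect_equal(ps$table$score, sort(ps$table$score, decreasing = TRUE))
  # the two 5-node paths tie at score 2.0: canonical (lexicographic on the
  # residue index sequence) puts 1-..-5 before 2-..-6
  tied <- ps$table[ps$table$length == 5, ]
  expect_equal(tied$source[1], "A:1")
  ps2 <- trace_paths(g, pairs, k = 2)
  expect_equal(length(ps2$paths), 2)
  ps3 <- trace_paths(g, pairs, k = 500)
  expect_identical(vapply(ps$paths, `[[`, character(1), "key"),
                   vapply(ps3$paths, `[[`, character(1), "key"))
})

test_that("path scores are invariant under reversal via canonical storage", {
  w <- matrix(NA_real_, 5, 5)
  for (i in 1:4) w[i, i + 1] <- w[i + 1, i] <- runif(1, 0.2, 0.8)
  fx <- graph_fixture(w)
  g <- build_graph(fx$nmi, fx$dist)
  p_fwd <- max_nmi_path(g, "A:1", "A:5")
  p_rev <- max_nmi_path(g, "A:5", "A:1")
  expect_identical(p_fwd$residues, p_rev$residues)
  expect_equal(p_fwd$score, p_rev$score)
  expect_identical(p_fwd$key, p_rev$key)
})

test_that("raising the contact cutoff only adds edges and never raises the optimal cost", {
  s <- make_chain_structure(10)
  d <- residue_min_distances(s)
  sim <- chain10_strong()$sim
  nmi <- nmi_matrix(sim$phi)
  cuts <- c(4.5, 5.5, 8)
  last_edges <- -1; last_cost <- Inf
  for (cc in cuts) {
    g <- build_graph(nmi, d, contact_cutoff = cc)
    expect_gte(igraph::ecount(g), last_edges)
    last_edges <- igraph::ecount(g)
    p <- max_nmi_path(g, "A:2", "A:10")
    cost <- sum(1 - igraph::E(g, path = p$residues)$nmi)
    # a superset of edges can only improve (lower) the minimized cost
    expect_lte(cost, last_cost + 1e-9)
    last_cost <- cost
  }
})

test_that("endpoint restriction filters pairs; contains restriction filters paths", {
  pairs <- data.frame(from = c("A:10", "A:5"), to = c("A:40", "A:40"),
                      stringsAsFactors = FALSE)
  uni <- c("A:5", "A:10", "A:40")
  kept <- filter_by_residues(pairs, "A:10", "endpoint", universe = uni)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$from, "A:10")
  # restriction = all residues is the identity
  expect_equal(nrow(filter_by_residues(pairs, uni, "endpoint",
                                       universe = uni)), 2)
  expect_error(filter_by_residues(pairs, "A:99", "endpoint", universe = uni),
               "A:99")
  # contains mode on a planted system: restricted paths are a subset with
  # identical scores
  fx <- chain10_strong()
  fit_paths <- trace_paths(
    build_graph(nmi_matrix(fx$sim$phi), residue_min_distances(fx$structure)),
    select_distant_pairs(residue_min_distances(fx$structure)), k = 500)
  restricted <- filter_by_residues(fit_paths, "A:6", "contains",
                                   universe = fx$structure$residues$label)
  expect_lte(length(restricted$paths), length(fit_paths$paths))
  all_keys <- vapply(fit_paths$paths, `[[`, character(1), "key")
  for (p in restricted$paths) {
    expect_true(p$key %in% all_keys)
    expect_equal(p$score, fit_paths$paths[[match(p$key, all_keys)]]$score)
  }
})

test_that("motif occurrence is the max member frequency, summed over replicas", {
  mk_path <- function(res) structure(list(residues = res, score = 1,
                                          key = paste(res, collapse = "-")),
                                     class = "ap_path")
  mk_set <- function(paths) structure(
    list(paths = paths, table = NULL, k = length(paths),
         n_candidates = length(paths), n_unreachable = 0L),
    class = "ap_pathset")
  ps1 <- mk_set(list(mk_path(c("A:10", "A:11")), mk_path(c("A:10", "A:12")),
                     mk_path(c("A:3", "A:4"))))
  rep1 <- motif_occurrence(ps1, list(m1 = c("A:10", "A:12")))
  expect_equal(rep1$occurrence, 2)        # A:10 in 2 paths, A:12 in 1
  expect_equal(rep1$top_residue, "A:10")
  # residues absent from every path
  expect_equal(motif_occurrence(ps1, list(m0 = "A:99"))$occurrence, 0)
  # replicas: per-residue frequencies summed, then maxed
  ps2 <- mk_set(list(mk_path(c("A:10", "A:5"))))
  ps3 <- mk_set(list(mk_path(c("A:12", "A:5")), mk_path(c("A:12", "A:6"))))
  rep3 <- motif_occurrence(list(ps1, ps2, ps3), list(m1 = c("A:10", "A:12")))
  expect_equal(rep3$occurrence, 3)        # A:10: 2+1+0; A:12: 1+0+2 -> max 3
  pr <- attr(rep3, "per_replica")
  expect_equal(unname(pr[1, ]), c(2, 1, 2))
  expect_error(motif_occurrence(ps1, list(m1 = "Z:1"), universe = "A:10"),
               "Z:1")
})
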