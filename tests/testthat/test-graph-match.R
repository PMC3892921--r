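# bare cleft construction helpers for graph-level unit tests
bare_cleft <- function(atoms) {
  structure(list(atoms = atoms, source = list(), bound_ligand = NULL),
            class = "cleft")
}

ca_cleft <- function(res_names, xyz) {
  n <- length(res_names)
  bare_cleft(data.frame(
    serial = seq_len(n), name = "CA", alt = "", res_name = res_names,
    chain = "A", res_seq = seq_len(n), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, element = "C",
    is_hetero = FALSE, is_hydrogen = FALSE, is_water = FALSE,
    class = "neutral", stringsAsFactors = FALSE))
}

typed_cleft <- function(classes, xyz, names = paste0("X", seq_along(classes))) {
  n <- length(classes)
  bare_cleft(data.frame(
    serial = seq_len(n), name = names, alt = "", res_name = "LIG",
    chain = "A", res_seq = seq_len(n), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, element = "C",
    is_hetero = TRUE, is_hydrogen = FALSE, is_water = FALSE,
    class = classes, stringsAsFactors = FALSE))
}

test_that("substitution compatibility follows the rank-order rule", {
  expect_true(jtt_compatible("LEU", "LEU", 5))
  expect_true(jtt_compatible("MSE", "MET", 5))
  # r = 20 makes every standard pair compatible (rank bound is total)
  combos <- expand.grid(a = c("TRP", "ASP", "GLY"), b = c("CYS", "ARG"))
  for (k in seq_len(nrow(combos)))
    expect_true(jtt_compatible(combos$a[k], combos$b[k], 20))
  # nonstandard residues only match themselves
  expect_true(jtt_compatible("U01", "U01", 5))
  expect_false(jtt_compatible("U01", "LEU", 5))

  # independent oracle: recompute the directed ranks from the shipped model
  raw <- read.delim(system.file("extdata", "jtt_model.tsv",
                                package = "cleftmatch"))
  aa <- raw$res[raw$res != "FREQ"]
  s <- as.matrix(raw[raw$res != "FREQ", aa]); rownames(s) <- aa
  freq <- as.numeric(raw[raw$res == "FREQ", aa])
  prob <- sweep(s, 2, freq, "*")
  rank_of <- function(a, b) {
    others <- setdiff(aa, a)
    which(others[order(-prob[a, others], others)] == b)
  }
  expect_false(min(rank_of("W", "D"), rank_of("D", "W")) <= 5)
  expect_false(jtt_compatible("TRP", "ASP", 5))
  for (pair in list(c("LEU", "ILE"), c("LYS", "ARG"), c("ASP", "GLU"))) {
    a3 <- pair[1]; b3 <- pair[2]
    a1 <- c(LEU = "L", ILE = "I", LYS = "K", ARG = "R", ASP = "D",
            GLU = "E")[a3]
    b1 <- c(LEU = "L", ILE = "I", LYS = "K", ARG = "R", ASP = "D",
            GLU = "E")[b3]
    expect_equal(jtt_compatible(a3, b3, 5),
                 min(rank_of(a1, b1), rank_of(b1, a1)) <= 5)
  }
})

test_that("stage-1 graph applies the Calpha distance-consistency rule", {
  # two residues per cleft, inter-Calpha distances 10.0 vs 13.4: edge;
  # 10.0 vs 13.6: no edge
  a <- ca_cleft(c("LEU", "LEU"), rbind(c(0, 0, 0), c(10, 0, 0)))
  b_edge <- ca_cleft(c("LEU", "LEU"), rbind(c(0, 0, 0), c(13.4, 0, 0)))
  b_none <- ca_cleft(c("LEU", "LEU"), rbind(c(0, 0, 0), c(13.6, 0, 0)))
  g1 <- build_stage1_graph(a, b_edge)
  k <- which(g1$nodes$i == 1 & g1$nodes$t == 1)
  l <- which(g1$nodes$i == 2 & g1$nodes$t == 2)
  expect_true(g1$adjacency[k, l])
  g2 <- build_stage1_graph(a, b_none)
  k <- which(g2$nodes$i == 1 & g2$nodes$t == 1)
  l <- which(g2$nodes$i == 2 & g2$nodes$t == 2)
  expect_false(g2$adjacency[k, l])

  # self-comparison: identity pairs form a clique covering every residue
  pair <- make_planted_cleft_pair(planted_pair_spec(k_common = 6,
                                                    n_noise_a = 0,
                                                    n_noise_b = 0,
                                                    jitter_sigma = 0,
                                                    seed = 5))
  g3 <- build_stage1_graph(pair$cleft_a, pair$cleft_a)
  cl <- max_clique(g3, "exact")
  expect_gte(length(cl), nrow(cleftmatch:::cleft_calpha(pair$cleft_a)))

  # no compatible residues -> empty node set
  g4 <- build_stage1_graph(ca_cleft("U01", matrix(0, 1, 3)),
                           ca_cleft("U02", matrix(0, 1, 3)))
  expect_equal(nrow(g4$nodes), 0)
})

test_that("stage-2 graph applies class identity, proximity and consistency", {
  # same class, 3.9 A apart -> node; 4.1 A -> no node
  a <- typed_cleft("donor", matrix(c(0, 0, 0), 1))
  b_near <- typed_cleft("donor", matrix(c(3.9, 0, 0), 1))
  b_far <- typed_cleft("donor", matrix(c(4.1, 0, 0), 1))
  b_class <- typed_cleft("acceptor", matrix(c(0, 0, 0), 1))
  expect_equal(nrow(build_stage2_graph(a, b_near)$nodes), 1)
  expect_equal(nrow(build_stage2_graph(a, b_far)$nodes), 0)
  expect_equal(nrow(build_stage2_graph(a, b_class)$nodes), 0)

  # distance difference 3.9 -> edge, 4.1 -> no edge
  a2 <- typed_cleft(c("donor", "donor"), rbind(c(0, 0, 0), c(10, 0, 0)))
  b2_edge <- typed_cleft(c("donor", "donor"), rbind(c(0, 0, 0), c(13.9, 0, 0)))
  b2_none <- typed_cleft(c("donor", "donor"), rbind(c(0, 0, 0), c(14.1, 0, 0)))
  g <- build_stage2_graph(a2, b2_edge)
  k <- which(g$nodes$i == 1 & g$nodes$t == 1)
  l <- which(g$nodes$i == 2 & g$nodes$t == 2)
  expect_true(g$adjacency[k, l])
  g <- build_stage2_graph(a2, b2_none)
  k <- which(g$nodes$i == 1 & g$nodes$t == 1)
  l <- which(g$nodes$i == 2 & g$nodes$t == 2)
  # 14.1 is beyond the 4 A node proximity for atom 2 as well, so the edge
  # cannot exist whether or not the node survives
  expect_true(length(l) == 0 || !g$adjacency[k, l])
})

test_that("clique search is exact on structured and random graphs", {
  full <- matrix(TRUE, 6, 6); diag(full) <- FALSE
  expect_length(max_clique(full, "exact"), 6)
  expect_length(max_clique(full, "abk"), 6)
  empty <- matrix(FALSE, 6, 6)
  expect_length(max_clique(empty, "exact"), 1)
  expect_length(max_clique(empty, "abk"), 1)

  set.seed(77)
  has_igraph <- requireNamespace("igraph", quietly = TRUE)
  for (rep in 1:40) {
    adj <- random_adjacency(12, 0.5)
    exact <- max_clique(adj, "exact")
    abk <- max_clique(adj, "abk")
    expect_equal(length(exact), brute_force_max_clique(adj))
    expect_lte(length(abk), length(exact))
    # both results really are cliques
    for (cl in list(exact, abk)) {
      if (length(cl) > 1) {
        sub <- adj[cl, cl]; diag(sub) <- TRUE
        expect_true(all(sub))
      }
    }
    if (has_igraph) {
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(length(exact), igraph::clique_num(g))
    }
  }
})

test_that("rigid superposition recovers exact and noisy motions", {
  set.seed(11)
  x <- matrix(runif(60, -10, 10), ncol = 3)
  # identity
  tr <- superpose_arun(x, x)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-9)
  # pure translation
  tr2 <- superpose_arun(x, sweep(x, 2, -c(5, -2, 1)))
  expect_equal(tr2$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr2$translation, c(5, -2, 1), tolerance = 1e-9)
  # random proper motion recovered to numerical precision
  for (rep in 1:5) {
    motion <- cleftmatch:::random_transform()
    y <- apply_transform(x, motion)
    fit <- superpose_arun(x, y)
    expect_lt(rmsd(apply_transform(x, fit), y), 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  expect_error(superpose_arun(x[1:2, ], x[1:2, ]),
               class = "cleftmatch_input_error")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_arun(line, line), "collinear")
})

test_that("rmsd matches its closed forms", {
  x <- matrix(runif(30), ncol = 3)
  expect_equal(rmsd(x, x), 0)
  expect_equal(rmsd(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1)), 2)
  expect_equal(rmsd(rbind(c(0, 0, 0), c(0, 0, 0)),
                    rbind(c(0, 0, 0), c(2, 0, 0))), sqrt(2))
  expect_error(rmsd(x, x[1:2, ]), class = "cleftmatch_input_error")
})

test_that("self-comparison is perfect and symmetric", {
  cleft <- simple_cleft(12, seed = 8)
  res <- compare_clefts(cleft, cleft)
  expect_equal(res$n_common, cleft_size(cleft))
  expect_equal(res$n_query, res$n_target)
  expect_equal(res$tanimoto, 1)
  expect_lt(max(res$correspondence$dist), 1e-9)

  pair <- make_planted_cleft_pair(planted_pair_spec(k_common = 12,
                                                    n_noise_a = 6,
                                                    n_noise_b = 6,
                                                    jitter_sigma = 0.2,
                                                    seed = 13))
  a <- type_cleft(pair$cleft_a); b <- type_cleft(pair$cleft_b)
  ab <- compare_clefts(a, b)
  ba <- compare_clefts(b, a)
  expect_equal(ab$n_common, ba$n_common)
})

test_that("comparison is invariant under rigid motion of the target", {
  cleft <- simple_cleft(12, seed = 9)
  base <- compare_clefts(cleft, cleft)
  set.seed(99)
  for (rep in 1:5) {
    motion <- cleftmatch:::random_transform()
    moved <- move_cleft(cleft, motion)
    res <- compare_clefts(cleft, moved)
    expect_equal(res$n_common, base$n_common)
    # recovered transform inverts the applied motion
    back <- apply_transform(as.matrix(moved$atoms[, c("x", "y", "z")]),
                            res$transform)
    expect_lt(rmsd(back, as.matrix(cleft$atoms[, c("x", "y", "z")])), 1e-6)
  }
})

test_that("planted common cores are recovered above the planted size", {
  pair <- make_planted_cleft_pair(planted_pair_spec(k_common = 20,
                                                    n_noise_a = 15,
                                                    n_noise_b = 15,
                                                    jitter_sigma = 0.2,
                                                    seed = 7))
  a <- type_cleft(pair$cleft_a); b <- type_cleft(pair$cleft_b)
  res <- compare_clefts(a, b)
  expect_gte(res$n_common, 20)
  # certificates, recomputed here rather than trusting the pipeline
  qi <- match(res$correspondence$query_serial, a$atoms$serial)
  ti <- match(res$correspondence$target_serial, b$atoms$serial)
  expect_true(all(a$atoms$class[qi] == b$atoms$class[ti]))
  dq <- as.matrix(dist(a$atoms[qi, c("x", "y", "z")]))
  dt <- as.matrix(dist(b$atoms[ti, c("x", "y", "z")]))
  expect_lte(max(abs(dq - dt)), 4 + 1e-9)
})

test_that("stage-1 failure yields a flagged zero-similarity result", {
  # incompatible synthetic residues on both sides: no stage-1 nodes
  a <- ca_cleft(c("U01", "U02", "U03", "U04"),
                matrix(runif(12, 0, 10), ncol = 3))
  b <- ca_cleft(c("V01", "V02", "V03", "V04"),
                matrix(runif(12, 0, 10), ncol = 3))
  a$atoms$class <- "neutral"; b$atoms$class <- "neutral"
  res <- compare_clefts(a, b)
  expect_true(res$no_superposition)
  expect_equal(res$n_common, 0)
  expect_equal(res$tanimoto, 0)
})
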