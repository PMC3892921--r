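# Two-stage association-graph matching of clefts.
#
# Stage 1 builds an association graph over Calpha atoms of substitutable
# residues (residue substitutability from the JTT model's rank-orders) and
# uses its largest clique to anchor a rigid superposition. Stage 2 builds an
# all-atom association graph over same-class atoms brought within a proximity
# cutoff by that superposition; its largest clique is the atomic
# correspondence whose size N_C measures similarity.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V", MSE = "M")

#' Matching parameters
#'
#' Defaults are the fixed operating point of the method: distance-consistency
#' slack \code{d_node_stage2} = 4 A (all-atom stage) and
#' \code{d_node_stage1} = 3.5 A (Calpha stage), residue-substitution
#' rank-order threshold \code{jtt_rank_max} = 5, post-superposition proximity
#' cutoff \code{proximity_n} = 4 A.
#'
#' @param d_node_stage2 edge consistency threshold, stage 2 (Angstrom).
#' @param d_node_stage1 edge consistency threshold, stage 1 (Angstrom).
#' @param jtt_rank_max maximum substitution rank-order r (1..20).
#' @param proximity_n stage-2 node proximity cutoff (Angstrom).
#' @param clique_mode \code{"exact"} (maximum clique) or \code{"abk"}
#'   (first maximal clique of the pivoting enumeration; near-optimal, fast).
#' @param max_nodes,max_edges exact-mode safety valve: larger association
#'   graphs fall back to \code{"abk"} with a warning.
#' @return List of class \code{match_params}.
#' @export
match_params <- function(d_node_stage2 = 4, d_node_stage1 = 3.5,
                         jtt_rank_max = 5, proximity_n = 4,
                         clique_mode = c("exact", "abk"),
                         max_nodes = 3000, max_edges = 5e6) {
  clique_mode <- match.arg(clique_mode)
  if (d_node_stage2 <= 0 || d_node_stage1 <= 0 || proximity_n <= 0)
    cm_input_error("match_params: distance thresholds must be positive")
  if (jtt_rank_max < 1 || jtt_rank_max > 20)
    cm_input_error("match_params: jtt_rank_max must be in [1, 20]")
  structure(list(d_node_stage2 = d_node_stage2, d_node_stage1 = d_node_stage1,
                 jtt_rank_max = jtt_rank_max, proximity_n = proximity_n,
                 clique_mode = clique_mode, max_nodes = max_nodes,
                 max_edges = max_edges),
            class = "match_params")
}

# --- JTT substitution rank-orders --------------------------------------------

jtt_env <- new.env(parent = emptyenv())

# Rank matrix: rank(a -> b) = position of b among the 19 substitution targets
# of a, ordered by substitution probability (proportional to exchangeability
# times target frequency) descending, ties alphabetical. Diagonal is 0
# (self-substitution always allowed).
jtt_rank_table <- function() {
  if (!is.null(jtt_env$rank)) return(jtt_env$rank)
  raw <- utils::read.delim(extdata("jtt_model.tsv"), stringsAsFactors = FALSE)
  aa <- raw$res[raw$res != "FREQ"]
  s <- as.matrix(raw[raw$res != "FREQ", aa])
  rownames(s) <- aa
  freq <- as.numeric(raw[raw$res == "FREQ", aa])
  prob <- sweep(s, 2, freq, "*") # P(a -> b) ~ s_ab * pi_b
  rank <- matrix(0L, 20, 20, dimnames = list(aa, aa))
  for (a in aa) {
    others <- setdiff(aa, a)
    ord <- others[order(-prob[a, others], others)]
    rank[a, ord] <- seq_along(ord)
  }
  jtt_env$rank <- rank
  rank
}

#' Residue substitutability under the JTT rank-order rule
#'
#' Two residues are compatible when the minimum of the two directed
#' substitution rank-orders is at most \code{r}; identical residues are
#' always compatible. Nonstandard residues are compatible only with
#' themselves.
#'
#' @param res_a,res_b 3-letter residue codes.
#' @param r rank-order threshold.
#' @return Logical.
#' @export
jtt_compatible <- function(res_a, res_b, r = 5) {
  a <- toupper(trimws(res_a)); b <- toupper(trimws(res_b))
  if (a == b) return(TRUE)
  a1 <- AA3[a]; b1 <- AA3[b]
  if (is.na(a1) || is.na(b1)) return(FALSE)
  if (a1 == b1) return(TRUE) # MSE ~ MET
  rk <- jtt_rank_table()
  min(rk[a1, b1], rk[b1, a1]) <= r
}

# Vectorized compatibility over the 20 standard codes (plus MSE).
jtt_compat_matrix <- function(codes_a, codes_b, r) {
  rk <- jtt_rank_table()
  a1 <- AA3[toupper(codes_a)]; b1 <- AA3[toupper(codes_b)]
  out <- matrix(FALSE, length(codes_a), length(codes_b))
  known_a <- !is.na(a1); known_b <- !is.na(b1)
  if (any(known_a) && any(known_b)) {
    ra <- rk[a1[known_a], b1[known_b], drop = FALSE]
    rb <- t(rk[b1[known_b], a1[known_a], drop = FALSE])
    out[known_a, known_b] <- pmin(ra, rb) <= r | ra == 0
  }
  same <- outer(toupper(codes_a), toupper(codes_b), "==")
  out | same
}

# --- Association graphs ------------------------------------------------------

new_association_graph <- function(nodes, adjacency, stage) {
  structure(list(nodes = nodes, adjacency = adjacency, stage = stage),
            class = "association_graph")
}

#' @export
print.association_graph <- function(x, ...) {
  cat(sprintf("<stage-%d association graph: %d nodes, %d edges>\n",
              x$stage, nrow(x$nodes), sum(x$adjacency) / 2))
  invisible(x)
}

assoc_graph_from_pairs <- function(ia, ib, da, db, d_node, stage) {
  nodes <- data.frame(i = ia, t = ib)
  n <- nrow(nodes)
  if (n == 0) return(new_association_graph(nodes, matrix(FALSE, 0, 0), stage))
  # |d_c(i,j) - d_c(t,s)| <= D_node, with distinct atoms on both sides
  adj <- abs(da[ia, ia, drop = FALSE] - db[ib, ib, drop = FALSE]) <= d_node
  adj <- adj & outer(ia, ia, "!=") & outer(ib, ib, "!=")
  diag(adj) <- FALSE
  new_association_graph(nodes, adj, stage)
}

#' Build the stage-1 (Calpha) association graph
#'
#' Nodes pair Calpha atoms of substitutable residues; edges require the
#' Calpha-Calpha distances on both sides to agree within
#' \code{d_node_stage1}.
#'
#' @param cleft_a,cleft_b validated clefts (each with >= 1 Calpha).
#' @param params a \code{match_params}.
#' @return An \code{association_graph} (stage 1); node columns \code{i},
#'   \code{t} index rows of the clefts' Calpha tables.
#' @export
build_stage1_graph <- function(cleft_a, cleft_b, params = match_params()) {
  ca_a <- cleft_calpha(cleft_a); ca_b <- cleft_calpha(cleft_b)
  if (!nrow(ca_a) || !nrow(ca_b))
    return(new_association_graph(data.frame(i = integer(), t = integer()),
                                 matrix(FALSE, 0, 0), 1L))
  compat <- jtt_compat_matrix(ca_a$res_name, ca_b$res_name, params$jtt_rank_max)
  idx <- which(compat, arr.ind = TRUE)
  da <- pair_dist(atom_xyz(ca_a)); db <- pair_dist(atom_xyz(ca_b))
  g <- assoc_graph_from_pairs(idx[, 1], idx[, 2], da, db,
                              params$d_node_stage1, 1L)
  g
}

#' Build the stage-2 (all-atom) association graph
#'
#' Operates on the non-Calpha atoms of both clefts, the second already moved
#' by the stage-1 superposition. Nodes pair atoms of identical interaction
#' class lying within \code{proximity_n} of each other; edges require
#' distance agreement within \code{d_node_stage2}.
#'
#' @param cleft_a query cleft (typed).
#' @param cleft_b_transformed target cleft (typed), in the query frame.
#' @param params a \code{match_params}.
#' @return An \code{association_graph} (stage 2); node columns index rows of
#'   the clefts' core (non-Calpha) atom tables.
#' @export
build_stage2_graph <- function(cleft_a, cleft_b_transformed,
                               params = match_params()) {
  a <- cleft_core(cleft_a); b <- cleft_core(cleft_b_transformed)
  if (is.null(a$class) || is.null(b$class))
    cm_input_error("stage-2 graph requires typed clefts")
  cross <- cross_dist(atom_xyz(a), atom_xyz(b))
  compat <- outer(a$class, b$class, "==") & cross <= params$proximity_n
  idx <- which(compat, arr.ind = TRUE)
  da <- pair_dist(atom_xyz(a)); db <- pair_dist(atom_xyz(b))
  assoc_graph_from_pairs(idx[, 1], idx[, 2], da, db, params$d_node_stage2, 2L)
}

# --- Clique detection --------------------------------------------------------

#' Largest clique of an association graph
#'
#' \code{"exact"} mode runs a deterministic branch-and-bound maximum-clique
#' search (greedy colouring bound, vertices in descending-degree order).
#' \code{"abk"} mode runs the pivoting maximal-clique enumeration
#' depth-first under the same pinned ordering and returns the \emph{first}
#' maximal clique emitted -- the enumeration's tendency to produce large
#' cliques early makes this near-optimal at a fraction of the cost. The ABK
#' result never exceeds the exact one.
#'
#' @param graph an \code{association_graph} (or square logical adjacency
#'   matrix).
#' @param mode \code{"exact"} or \code{"abk"}.
#' @return Integer vector of node indices (pairwise adjacent; length >= 1
#'   whenever the graph has a node; empty for an empty graph).
#' @export
max_clique <- function(graph, mode = c("exact", "abk")) {
  mode <- match.arg(mode)
  adj <- if (inherits(graph, "association_graph")) graph$adjacency else graph
  n <- nrow(adj)
  if (n == 0) return(integer())
  if (n == 1) return(1L)
  clique <- if (mode == "exact") max_clique_exact(adj) else first_maximal_clique(adj)
  if (length(clique) > 1) {
    sub <- adj[clique, clique, drop = FALSE]
    diag(sub) <- TRUE
    if (!all(sub)) cm_runtime_error("internal error: clique certificate failed")
  }
  sort(clique)
}

# Pinned deterministic vertex order: descending degree, ties by index.
vertex_order <- function(adj) order(-rowSums(adj), seq_len(nrow(adj)))

max_clique_exact <- function(adj) {
  n <- nrow(adj)
  ord <- vertex_order(adj)
  best <- integer()
  nbrs <- lapply(seq_len(n), function(v) which(adj[v, ]))

  expand <- function(r, p) {
    if (!length(p)) {
      if (length(r) > length(best)) best <<- r
      return()
    }
    # greedy sequential colouring of p (in given order) for the bound
    colour <- integer(length(p))
    for (k in seq_along(p)) {
      used <- colour[which(adj[p[k], p[seq_len(k - 1)]])]
      c0 <- 1L
      while (c0 %in% used) c0 <- c0 + 1L
      colour[k] <- c0
    }
    o <- order(colour, seq_along(p))
    p <- p[o]; colour <- colour[o]
    for (k in rev(seq_along(p))) {
      if (length(r) + colour[k] <= length(best)) return()
      v <- p[k]
      expand(c(r, v), intersect(p[seq_len(k - 1)], nbrs[[v]]))
    }
  }
  expand(integer(), ord)
  best
}

first_maximal_clique <- function(adj) {
  n <- nrow(adj)
  ord <- vertex_order(adj)
  nbrs <- lapply(seq_len(n), function(v) which(adj[v, ]))
  found <- NULL

  bk <- function(r, p, x) {
    if (!is.null(found)) return()
    if (!length(p) && !length(x)) { found <<- r; return() }
    # candidates ordered by connectivity within P (ties by node index): the
    # first branch then grows through the densest region, which is what
    # makes the first maximal clique emitted (near-)maximum
    overlap_p <- vapply(p, function(v) length(intersect(p, nbrs[[v]])), 0L)
    p <- p[order(-overlap_p, p)]
    cand <- c(p, x)
    # pivot: candidate with the most neighbours inside P
    overlap <- vapply(cand, function(u) length(intersect(p, nbrs[[u]])), 0L)
    u <- cand[which.max(overlap)]
    for (v in setdiff(p, nbrs[[u]])) {
      bk(c(r, v), intersect(p, nbrs[[v]]), intersect(x, nbrs[[v]]))
      if (!is.null(found)) return()
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(), ord, integer())
  found
}

# --- Full two-stage comparison -----------------------------------------------

#' Compare two clefts and produce their atomic correspondence
#'
#' Runs the full two-stage pipeline: stage-1 Calpha association graph and
#' clique, rigid superposition from the Calpha clique, stage-2 all-atom
#' association graph and clique, then a final re-fit of the transform on the
#' stage-2 correspondence. Both the class identity and the pairwise
#' distance-consistency certificate of every reported correspondence are
#' asserted on output.
#'
#' @param query,target validated clefts (typed automatically if needed).
#' @param params a \code{match_params}.
#' @return Object of class \code{similarity_result}: \code{n_common} (N_C),
#'   \code{n_query} (N_A), \code{n_target} (N_B), \code{tanimoto},
#'   \code{transform} (maps target onto query; NULL when stage 1 fails),
#'   \code{correspondence} (data.frame), \code{ligand_rmsd} (NA when not
#'   computable), \code{no_superposition}, \code{stage1_size},
#'   \code{clique_mode} (mode actually used).
#' @export
compare_clefts <- function(query, target, params = match_params()) {
  validate_cleft(query); validate_cleft(target)
  if (!is_typed(query)) query <- type_cleft(query)
  if (!is_typed(target)) target <- type_cleft(target)
  mode <- params$clique_mode

  n_a <- cleft_size(query); n_b <- cleft_size(target)
  empty <- function(flag) {
    structure(list(n_common = 0L, n_query = n_a, n_target = n_b,
                   tanimoto = 0, transform = NULL,
                   correspondence = NULL, ligand_rmsd = NA_real_,
                   no_superposition = flag, stage1_size = 0L,
                   clique_mode = mode),
              class = "similarity_result")
  }

  g1 <- build_stage1_graph(query, target, params)
  if (!nrow(g1$nodes)) return(empty(TRUE))
  mode1 <- valve_mode(g1, mode, params)
  cl1 <- max_clique(g1, mode1)
  if (length(cl1) < 3) return(empty(TRUE))

  ca_q <- cleft_calpha(query); ca_t <- cleft_calpha(target)
  pairs1 <- g1$nodes[cl1, , drop = FALSE]
  tr1 <- tryCatch(
    superpose_arun(atom_xyz(ca_t)[pairs1$t, , drop = FALSE],
                   atom_xyz(ca_q)[pairs1$i, , drop = FALSE]),
    cleftmatch_input_error = function(e) NULL)
  if (is.null(tr1)) return(empty(TRUE))

  moved <- target
  moved$atoms[, c("x", "y", "z")] <- apply_transform(atom_xyz(target$atoms), tr1)

  g2 <- build_stage2_graph(query, moved, params)
  res <- empty(FALSE)
  res$stage1_size <- length(cl1)
  res$transform <- tr1
  if (!nrow(g2$nodes)) return(res)
  mode2 <- valve_mode(g2, mode, params)
  cl2 <- max_clique(g2, mode2)

  core_q <- cleft_core(query); core_t <- cleft_core(target)
  pairs2 <- g2$nodes[cl2, , drop = FALSE]
  n_c <- nrow(pairs2)

  # final transform: re-fit on the stage-2 correspondence (original target
  # coordinates) when it can define one; otherwise keep the stage-1 fit
  tr <- tr1
  if (n_c >= 3) {
    tr2 <- tryCatch(
      superpose_arun(atom_xyz(core_t)[pairs2$t, , drop = FALSE],
                     atom_xyz(core_q)[pairs2$i, , drop = FALSE]),
      cleftmatch_input_error = function(e) NULL)
    if (!is.null(tr2)) tr <- tr2
  }

  fitted_t <- apply_transform(atom_xyz(core_t)[pairs2$t, , drop = FALSE], tr)
  corr <- data.frame(
    query_serial = core_q$serial[pairs2$i],
    query_atom = atom_label(core_q[pairs2$i, , drop = FALSE]),
    target_serial = core_t$serial[pairs2$t],
    target_atom = atom_label(core_t[pairs2$t, , drop = FALSE]),
    class = core_q$class[pairs2$i],
    dist = sqrt(rowSums((atom_xyz(core_q)[pairs2$i, , drop = FALSE] -
                           fitted_t)^2)),
    stringsAsFactors = FALSE
  )

  assert_correspondence(core_q, core_t, pairs2, params$d_node_stage2)

  res$n_common <- n_c
  res$n_query <- n_a; res$n_target <- n_b
  res$tanimoto <- tanimoto(n_c, n_a, n_b)
  res$transform <- tr
  res$correspondence <- corr
  res$clique_mode <- mode2
  res$ligand_rmsd <- ligand_rmsd(query, target, tr)
  res
}

valve_mode <- function(graph, mode, params) {
  if (mode == "exact") {
    n <- nrow(graph$nodes)
    e <- sum(graph$adjacency) / 2
    if (n > params$max_nodes || e > params$max_edges) {
      cm_warn("association graph too large for exact search (%d nodes, %d edges); using abk",
              n, e)
      return("abk")
    }
  }
  mode
}

atom_label <- function(atoms) {
  dash <- function(v) ifelse(nzchar(v), v, "-")
  sprintf("%s%d%s-:%s", atoms$res_name, atoms$res_seq, dash(atoms$chain),
          atoms$name)
}

# Certificates: every matched pair has identical class; all pairwise
# distance differences satisfy the stage-2 consistency bound.
assert_correspondence <- function(core_q, core_t, pairs, d_node) {
  if (!all(core_q$class[pairs$i] == core_t$class[pairs$t]))
    cm_runtime_error("internal error: type certificate violated")
  if (nrow(pairs) > 1) {
    dq <- pair_dist(atom_xyz(core_q)[pairs$i, , drop = FALSE])
    dt <- pair_dist(atom_xyz(core_t)[pairs$t, , drop = FALSE])
    if (max(abs(dq - dt)) > d_node + 1e-9)
      cm_runtime_error("internal error: distance-consistency certificate violated")
  }
  invisible(TRUE)
}

# RMSD between equivalent bound-ligand atoms after superposition. Atoms are
# paired by name when both ligands share a het code, otherwise greedily by
# nearest same-element pairs within 3 A.
ligand_rmsd <- function(query, target, transform) {
  lq <- query$bound_ligand; lt <- target$bound_ligand
  if (is.null(lq) || is.null(lt) || is.null(transform)) return(NA_real_)
  xt <- apply_transform(atom_xyz(lt), transform)
  if (identical(sort(unique(lq$res_name)), sort(unique(lt$res_name)))) {
    m <- match(paste(lq$res_name, lq$name), paste(lt$res_name, lt$name))
    ok <- !is.na(m)
    if (sum(ok) >= 1 && !anyDuplicated(m[ok]))
      return(rmsd(atom_xyz(lq)[ok, , drop = FALSE], xt[m[ok], , drop = FALSE]))
  }
  d <- cross_dist(atom_xyz(lq), xt)
  d[outer(lq$element, lt$element, "!=")] <- Inf
  pairs <- greedy_pairs(d, 3)
  if (!nrow(pairs)) return(NA_real_)
  rmsd(atom_xyz(lq)[pairs[, 1], , drop = FALSE], xt[pairs[, 2], , drop = FALSE])
}

greedy_pairs <- function(d, cutoff) {
  out <- matrix(integer(), 0, 2)
  while (TRUE) {
    k <- which.min(d)
    if (!length(k) || !is.finite(d[k]) || d[k] > cutoff) break
    i <- (k - 1) %% nrow(d) + 1
    j <- (k - 1) %/% nrow(d) + 1
    out <- rbind(out, c(i, j))
    d[i, ] <- Inf; d[, j] <- Inf
  }
  out
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity: N_C=%d N_A=%d N_B=%d T=%.3f%s%s>\n",
              x$n_common, x$n_query, x$n_target, x$tanimoto,
              if (is.na(x$ligand_rmsd)) "" else
                sprintf(" ligand RMSD=%.2f A", x$ligand_rmsd),
              if (x$no_superposition) " [no superposition]" else ""))
  invisible(x)
}

#' Tabular dump of a correspondence
#'
#' @param result a \code{similarity_result}.
#' @param file optional path for the tab-separated table.
#' @return The correspondence data.frame, invisibly when written.
#' @export
write_correspondence <- function(result, file = NULL) {
  corr <- result$correspondence
  if (is.null(corr)) corr <- data.frame()
  if (!is.null(file)) {
    utils::write.table(format(corr, digits = 6), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(corr))
  }
  corr
}
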