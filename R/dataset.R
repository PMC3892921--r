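# Target dataset handling and the query-versus-dataset search.
#
# A dataset is a directory with a tab-separated index (columns pdb_code,
# ligand_code, pfam_acc, cognate_similarity) and one PDB fragment per entry,
# named <pdb>_<ligand>.pdb: ATOM records give the binding-site residues
# (Calphas included), HETATM records the bound ligand.

#' Load a binding-site target dataset
#'
#' Entries whose cleft fails validation are skipped with a warning; the
#' count of skips is reported. Alternative index layouts can be read by
#' remapping column names via \code{col_map}.
#'
#' @param path dataset root directory.
#' @param index index file name within \code{path}.
#' @param col_map named character vector mapping the required fields
#'   (\code{pdb_code}, \code{ligand_code}, \code{pfam_acc},
#'   \code{cognate_similarity}) to the index's column names.
#' @return List of \code{dataset_entry} objects (fields \code{pdb_code},
#'   \code{ligand_code}, \code{pfam_acc}, \code{cognate_similarity},
#'   \code{cleft}).
#' @export
load_dataset <- function(path, index = "index.tsv",
                         col_map = c(pdb_code = "pdb_code",
                                     ligand_code = "ligand_code",
                                     pfam_acc = "pfam_acc",
                                     cognate_similarity = "cognate_similarity")) {
  index_path <- file.path(path, index)
  if (!file.exists(index_path))
    cm_input_error("missing dataset index: '%s'", index_path)
  idx <- utils::read.delim(index_path, stringsAsFactors = FALSE)
  need <- col_map[c("pdb_code", "ligand_code", "pfam_acc", "cognate_similarity")]
  if (!all(need %in% names(idx)))
    cm_input_error("dataset index lacks column(s): %s",
                   paste(setdiff(need, names(idx)), collapse = ", "))
  entries <- list()
  skipped <- 0L
  for (k in seq_len(nrow(idx))) {
    pdb <- as.character(idx[[need["pdb_code"]]][k])
    lig <- as.character(idx[[need["ligand_code"]]][k])
    entry_file <- file.path(path, sprintf("%s_%s.pdb", pdb, lig))
    entry <- tryCatch({
      if (!file.exists(entry_file))
        cm_input_error("entry file missing: %s", entry_file)
      str <- read_pdb_file(entry_file)
      cleft <- cleft_from_structure(str, source = list(id = pdb, ligand = lig))
      cleft <- type_cleft(cleft)
      cog <- as.numeric(idx[[need["cognate_similarity"]]][k])
      if (!is.finite(cog) || cog < 0 || cog > 1)
        cm_input_error("cognate similarity out of [0,1]: %s", cog)
      structure(list(pdb_code = pdb, ligand_code = lig,
                     pfam_acc = as.character(idx[[need["pfam_acc"]]][k]),
                     cognate_similarity = cog, cleft = cleft),
                class = "dataset_entry")
    }, cleftmatch_input_error = function(e) {
      cm_warn("skipping entry %s/%s: %s", pdb, lig, conditionMessage(e))
      NULL
    })
    if (is.null(entry)) skipped <- skipped + 1L else
      entries[[length(entries) + 1L]] <- entry
  }
  message(sprintf("loaded %d dataset entries (%d skipped)",
                  length(entries), skipped))
  entries
}

#' Filter dataset entries by cognate-ligand similarity
#'
#' Keeps entries with \code{cognate_similarity >= threshold}, preserving
#' order. Higher thresholds shrink the searched dataset.
#'
#' @param entries list of \code{dataset_entry}.
#' @param threshold fraction in [0, 1].
#' @return Filtered list.
#' @export
filter_cognate <- function(entries, threshold) {
  if (threshold < 0 || threshold > 1)
    cm_input_error("cognate threshold must be in [0, 1]")
  Filter(function(e) e$cognate_similarity >= threshold, entries)
}

#' Search a query cleft against a target dataset
#'
#' Compares the query against every entry, computes Z-scores and p-values
#' over the resulting populations of N_C and Tanimoto scores (trimmed
#' statistics; the p-value is the extreme-value tail probability of the
#' reported Z), and ranks hits by Tanimoto descending (ties by N_C
#' descending, then PDB code).
#'
#' @param query a validated, typed \code{cleft}.
#' @param entries list of \code{dataset_entry} (non-empty).
#' @param params a \code{match_params}.
#' @param top_k number of hits returned.
#' @param per_pfam keep only the best hit of each Pfam family before
#'   truncation.
#' @param sort_by \code{"tanimoto"} (default) or \code{"n_common"}.
#' @return Object of class \code{search_hits}: \code{hits} (data.frame with
#'   one row per returned hit), \code{results} (matching
#'   \code{similarity_result} list), \code{population} (all scores + trim
#'   statistics), \code{n_compared}.
#' @export
run_search <- function(query, entries, params = match_params(), top_k = 10,
                       per_pfam = FALSE, sort_by = c("tanimoto", "n_common")) {
  sort_by <- match.arg(sort_by)
  if (!length(entries)) cm_input_error("run_search: empty target dataset")
  validate_cleft(query)
  if (!is_typed(query)) query <- type_cleft(query)

  results <- lapply(entries, function(e) compare_clefts(query, e$cleft, params))
  nc <- vapply(results, function(r) as.numeric(r$n_common), 0)
  tt <- vapply(results, function(r) r$tanimoto, 0)

  if (length(entries) >= 2) {
    tz_nc <- trimmed_z(nc)
    tz_t <- trimmed_z(tt)
    z_nc <- tz_nc$z; z_t <- tz_t$z
  } else {
    tz_nc <- tz_t <- list(stats = list(degenerate = TRUE, n_trim_iters = 0L,
                                       trimmed_count = 0L))
    z_nc <- z_t <- 0
  }
  p_nc <- ifelse(rep(tz_nc$stats$degenerate, length(z_nc)), 1, evd_pvalue(z_nc))
  p_t <- ifelse(rep(tz_t$stats$degenerate, length(z_t)), 1, evd_pvalue(z_t))

  hits <- data.frame(
    pdb_code = vapply(entries, function(e) e$pdb_code, ""),
    ligand_code = vapply(entries, function(e) e$ligand_code, ""),
    pfam_acc = vapply(entries, function(e) e$pfam_acc, ""),
    cognate_similarity = vapply(entries, function(e) e$cognate_similarity, 0),
    n_common = as.integer(nc),
    z_nc = z_nc, p_nc = p_nc,
    tanimoto = tt,
    z_t = z_t, p_t = p_t,
    ligand_rmsd = vapply(results, function(r) r$ligand_rmsd, 0),
    stringsAsFactors = FALSE
  )
  ord <- if (sort_by == "tanimoto") {
    order(-hits$tanimoto, -hits$n_common, hits$pdb_code)
  } else {
    order(-hits$n_common, -hits$tanimoto, hits$pdb_code)
  }
  hits <- hits[ord, , drop = FALSE]
  results <- results[ord]
  if (per_pfam) {
    first <- !duplicated(hits$pfam_acc)
    hits <- hits[first, , drop = FALSE]
    results <- results[first]
  }
  keep <- seq_len(min(top_k, nrow(hits)))
  hits <- hits[keep, , drop = FALSE]
  results <- results[keep]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL

  structure(list(hits = hits, results = results,
                 population = list(n_common = nc, tanimoto = tt,
                                   stats_nc = tz_nc$stats,
                                   stats_t = tz_t$stats),
                 n_compared = length(entries),
                 query_source = query$source, params = params),
            class = "search_hits")
}

#' @export
print.search_hits <- function(x, ...) {
  cat(sprintf("search over %d entries; top %d hits:\n", x$n_compared,
              nrow(x$hits)))
  print(x$hits[, c("rank", "pdb_code", "ligand_code", "n_common", "z_nc",
                   "p_nc", "tanimoto", "z_t", "p_t")], digits = 3)
  invisible(x)
}

# --- Ligand molecular graphs -------------------------------------------------

#' Infer covalent bonds from interatomic distances
#'
#' Two heavy atoms are bonded when their distance is at most the sum of
#' their covalent radii plus 0.45 A.
#'
#' @param atoms atom data.frame (>= 1 heavy atom).
#' @return Object of class \code{molecular_graph}: \code{atoms},
#'   \code{adjacency} (symmetric logical, no self-edges), \code{edges}
#'   (two-column index matrix).
#' @export
infer_bonds <- function(atoms) {
  atoms <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  if (!nrow(atoms)) cm_input_error("infer_bonds: no heavy atoms")
  d <- pair_dist(atom_xyz(atoms))
  lim <- outer(covalent_radius(atoms$element), covalent_radius(atoms$element),
               "+") + BOND_TOL
  adj <- d <= lim & d > 0
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure(list(atoms = atoms, adjacency = adj,
                 edges = unname(idx[, c(1, 2), drop = FALSE])),
            class = "molecular_graph")
}

# Element-labelled linear path fingerprint, hashed into a fixed-width bit
# set. Paths of 1..(max_len+1) atoms are enumerated; each path contributes
# the lexicographically smaller of its forward/reverse element strings.
FP_BITS <- 1024L

path_fingerprint <- function(graph, max_len = 7L) {
  el <- toupper(graph$atoms$element)
  adj <- graph$adjacency
  n <- length(el)
  labels <- new.env(parent = emptyenv())
  add_label <- function(path) {
    fwd <- paste(el[path], collapse = "-")
    rev_ <- paste(rev(el[path]), collapse = "-")
    lab <- if (fwd <= rev_) fwd else rev_
    assign(lab, TRUE, envir = labels)
  }
  walk <- function(path) {
    add_label(path)
    if (length(path) > max_len) return()
    v <- path[length(path)]
    for (w in which(adj[v, ])) {
      if (w %in% path) next
      walk(c(path, w))
    }
  }
  for (v in seq_len(n)) walk(v)
  bits <- rep(FALSE, FP_BITS)
  for (lab in ls(labels)) bits[string_hash(lab) + 1L] <- TRUE
  bits
}

# Deterministic 31-based rolling string hash modulo the fingerprint width.
string_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% FP_BITS
  as.integer(h)
}

#' Topological similarity of two ligands
#'
#' Tanimoto coefficient over element-labelled path fingerprints (paths of up
#' to eight atoms, hashed to a 1024-bit set). A comparative aid for judging
#' whether top hits bind chemically related ligands; symmetric, with
#' self-similarity 1.
#'
#' @param a,b \code{molecular_graph} objects (from \code{infer_bonds}).
#' @return Fraction in [0, 1].
#' @export
ligand_topo_similarity <- function(a, b) {
  fa <- path_fingerprint(a)
  fb <- path_fingerprint(b)
  un <- sum(fa | fb)
  if (un == 0) return(0)
  sum(fa & fb) / un
}

# --- Report bundle -----------------------------------------------------------

#' Write a search report bundle
#'
#' Writes the hit table (\code{hits.tsv}: pdb, ligand, N_C, z_nc, p_nc, T,
#' z_t, p_t), one superposed-ligand PDB file and one correspondence table
#' per hit, and the pairwise target-ligand topological similarity matrix
#' (\code{ligand_similarity.tsv}).
#'
#' @param search a \code{search_hits}.
#' @param entries the entry list the search ran over (for ligand atoms).
#' @param out_dir output directory (created if needed).
#' @return Invisible list of written paths.
#' @export
report <- function(search, entries, out_dir) {
  if (!nrow(search$hits)) cm_input_error("report: no hits to report")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    cm_input_error("cannot create output directory '%s'", out_dir)
  hits <- search$hits
  paths <- list()

  tab <- data.frame(pdb = hits$pdb_code, ligand = hits$ligand_code,
                    N_C = hits$n_common,
                    z_nc = sprintf("%.6g", hits$z_nc),
                    p_nc = sprintf("%.6g", hits$p_nc),
                    T = sprintf("%.6g", hits$tanimoto),
                    z_t = sprintf("%.6g", hits$z_t),
                    p_t = sprintf("%.6g", hits$p_t),
                    stringsAsFactors = FALSE)
  paths$hits <- file.path(out_dir, "hits.tsv")
  utils::write.table(tab, paths$hits, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  key <- vapply(entries, function(e) paste(e$pdb_code, e$ligand_code), "")
  graphs <- list()
  for (k in seq_len(nrow(hits))) {
    ek <- match(paste(hits$pdb_code[k], hits$ligand_code[k]), key)
    entry <- entries[[ek]]
    res <- search$results[[k]]
    stem <- sprintf("%02d_%s_%s", k, hits$pdb_code[k], hits$ligand_code[k])
    lig <- entry$cleft$bound_ligand
    if (!is.null(lig) && !is.null(res$transform)) {
      p <- file.path(out_dir, paste0(stem, "_ligand.pdb"))
      write_pdb(lig, transform = res$transform, file = p)
      paths[[paste0("ligand_", k)]] <- p
    }
    p <- file.path(out_dir, paste0(stem, "_correspondence.tsv"))
    write_correspondence(res, p)
    paths[[paste0("corr_", k)]] <- p
    graphs[[k]] <- if (is.null(lig)) NULL else infer_bonds(lig)
  }

  m <- length(graphs)
  sim <- matrix(NA_real_, m, m)
  lab <- paste(hits$pdb_code, hits$ligand_code, sep = "_")
  dimnames(sim) <- list(lab, lab)
  for (i in seq_len(m)) for (j in i:m) {
    if (is.null(graphs[[i]]) || is.null(graphs[[j]])) next
    sim[i, j] <- sim[j, i] <-
      if (i == j) 1 else ligand_topo_similarity(graphs[[i]], graphs[[j]])
  }
  paths$ligand_similarity <- file.path(out_dir, "ligand_similarity.tsv")
  utils::write.table(round(sim, 4), paths$ligand_similarity, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(paths)
}
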