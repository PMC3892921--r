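# One small synthetic dataset shared by the tests in this file.
local_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- planted_pair_spec(k_common = 12, n_noise_a = 6, n_noise_b = 6,
                                jitter_sigma = 0.2, seed = 21)
      cache <<- suppressMessages(
        make_synthetic_dataset(12, 3, spec, seed = 17))
    }
    cache
  }
})

test_that("datasets load, validate and skip malformed entries", {
  ds <- local_dataset()
  expect_message(entries <- load_dataset(ds$root), "12 dataset entries")
  expect_length(entries, 12)
  expect_true(all(vapply(entries, function(e)
    cleftmatch:::is_typed(e$cleft), TRUE)))

  # corrupt copy: one 3-atom entry and one missing file are skipped
  root2 <- tempfile("ds_bad_")
  dir.create(root2)
  file.copy(list.files(ds$root, full.names = TRUE), root2)
  idx <- read.delim(file.path(root2, "index.tsv"))
  writeLines(c(pdb_line(1, "N", "GLY", 1, 0, 0, 0),
               pdb_line(2, "CA", "GLY", 1, 1.4, 0, 0),
               pdb_line(3, "C", "GLY", 1, 2.8, 0, 0), "END"),
             file.path(root2, "bad1_LXX.pdb"))
  idx <- rbind(idx,
               data.frame(pdb_code = c("bad1", "bad2"),
                          ligand_code = c("LXX", "LYY"),
                          pfam_acc = "PF99999", cognate_similarity = 0.5))
  write.table(idx, file.path(root2, "index.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  w <- capture_warnings(expect_message(e2 <- load_dataset(root2), "2 skipped"))
  expect_length(w, 2)
  expect_true(all(grepl("skipping entry", w)))
  expect_length(e2, 12)

  expect_error(load_dataset(tempfile()), class = "cleftmatch_input_error")
})

test_that("cognate filtering is exact on the assigned grid and monotone", {
  ds <- local_dataset()
  entries <- suppressMessages(load_dataset(ds$root))
  cs <- vapply(entries, function(e) e$cognate_similarity, 0)
  expect_equal(cs, ds$index$cognate_similarity)
  expect_length(filter_cognate(entries, 0), length(entries))
  for (th in c(0.25, 0.5, 0.95)) {
    kept <- filter_cognate(entries, th)
    expect_length(kept, sum(cs >= th))
    expect_true(all(vapply(kept, function(e) e$cognate_similarity, 0) >= th))
  }
  expect_length(filter_cognate(entries, 1), sum(cs >= 1))
  # monotone: higher threshold keeps a subset
  k1 <- vapply(filter_cognate(entries, 0.3), function(e) e$pdb_code, "")
  k2 <- vapply(filter_cognate(entries, 0.6), function(e) e$pdb_code, "")
  expect_true(all(k2 %in% k1))
})

test_that("self-retrieval ranks the entry's own cleft first with T = 1", {
  ds <- local_dataset()
  entries <- suppressMessages(load_dataset(ds$root))
  query <- entries[[1]]$cleft
  hits <- run_search(query, entries, top_k = 5)
  expect_equal(hits$hits$pdb_code[1], entries[[1]]$pdb_code)
  expect_equal(hits$hits$tanimoto[1], 1)
  expect_equal(hits$hits$n_common[1], cleft_size(query))
})

test_that("search ranks planted entries on top, deterministically", {
  ds <- local_dataset()
  entries <- suppressMessages(load_dataset(ds$root))
  hits <- run_search(ds$query, entries, top_k = 12)
  n_planted <- length(ds$planted)
  expect_setequal(hits$hits$pdb_code[seq_len(n_planted)], ds$planted)
  # ranking keys: T desc, then N_C desc, then pdb code
  expect_true(all(diff(hits$hits$tanimoto) <= 1e-12))
  # bit-reproducible on a re-run
  hits2 <- run_search(ds$query, entries, top_k = 12)
  expect_identical(hits$hits, hits2$hits)
  # internal consistency: reported p equals the EVD tail of the reported z
  expect_identical(hits$hits$p_t, evd_pvalue(hits$hits$z_t))
  expect_identical(hits$hits$p_nc, evd_pvalue(hits$hits$z_nc))
})

test_that("per-Pfam collapsing keeps one hit per family", {
  ds <- local_dataset()
  entries <- suppressMessages(load_dataset(ds$root))
  plain <- run_search(ds$query, entries, top_k = 12)
  collapsed <- run_search(ds$query, entries, top_k = 12, per_pfam = TRUE)
  expect_false(any(duplicated(collapsed$hits$pfam_acc)))
  # entries s001/s002 share a family; only the better one survives
  expect_lt(nrow(collapsed$hits), nrow(plain$hits))
  best_shared <- plain$hits[plain$hits$pfam_acc == plain$hits$pfam_acc[1], ]
  expect_equal(collapsed$hits$pdb_code[collapsed$hits$pfam_acc ==
                                         best_shared$pfam_acc[1]],
               best_shared$pdb_code[1])
})

test_that("bond inference follows the covalent-radius rule", {
  two_c <- function(d) parse_pdb(paste(c(
    pdb_line(1, "C1", "LIG", 1, 0, 0, 0, het = TRUE),
    pdb_line(2, "C2", "LIG", 1, d, 0, 0, het = TRUE), "END"),
    collapse = "\n"))$atoms
  expect_equal(nrow(infer_bonds(two_c(1.5))$edges), 1)
  expect_equal(nrow(infer_bonds(two_c(2.5))$edges), 0)

  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  benzene <- parse_pdb(paste(c(vapply(1:6, function(k)
    pdb_line(k, paste0("C", k), "BNZ", 1, 1.39 * cos(th[k]),
             1.39 * sin(th[k]), 0, het = TRUE), ""), "END"),
    collapse = "\n"))$atoms
  g <- infer_bonds(benzene)
  expect_equal(nrow(g$edges), 6)
  expect_true(all(rowSums(g$adjacency) == 2)) # one 6-cycle
  expect_true(isSymmetric(g$adjacency))
  expect_false(any(diag(g$adjacency)))
})

test_that("ligand topological similarity is a sane comparative measure", {
  chain_mol <- function(elements) {
    lines <- vapply(seq_along(elements), function(k)
      pdb_line(k, paste0(elements[k], k), "LIG", 1, 1.45 * k, 0, 0,
               het = TRUE), "")
    infer_bonds(parse_pdb(paste(c(lines, "END"), collapse = "\n"))$atoms)
  }
  atp_like <- chain_mol(c("N", "C", "N", "C", "C", "O", "P", "O", "P", "O", "P"))
  adp_like <- chain_mol(c("N", "C", "N", "C", "C", "O", "P", "O", "P"))
  benzene <- chain_mol(rep("C", 6))
  expect_equal(ligand_topo_similarity(atp_like, atp_like), 1)
  s_ab <- ligand_topo_similarity(atp_like, adp_like)
  s_ax <- ligand_topo_similarity(atp_like, benzene)
  expect_gt(s_ab, s_ax)
  expect_equal(s_ab, ligand_topo_similarity(adp_like, atp_like))
  # disjoint single atoms share no features
  expect_equal(ligand_topo_similarity(chain_mol("C"), chain_mol("N")), 0)
})

test_that("the report bundle is complete and internally consistent", {
  ds <- local_dataset()
  entries <- suppressMessages(load_dataset(ds$root))
  query <- entries[[1]]$cleft
  hits <- run_search(query, entries, top_k = 4)
  out <- tempfile("report_")
  paths <- report(hits, entries, out)
  expect_true(file.exists(file.path(out, "hits.tsv")))
  tab <- read.delim(file.path(out, "hits.tsv"))
  expect_equal(names(tab), c("pdb", "ligand", "N_C", "z_nc", "p_nc",
                             "T", "z_t", "p_t"))
  expect_equal(nrow(tab), 4)
  expect_length(list.files(out, pattern = "_ligand\\.pdb$"), 4)
  expect_length(list.files(out, pattern = "_correspondence\\.tsv$"), 4)

  # the self-hit's superposed ligand reproduces the query's bound ligand
  self_row <- which(hits$hits$pdb_code == entries[[1]]$pdb_code)
  lig_file <- list.files(out, pattern = sprintf("^%02d_.*_ligand\\.pdb$",
                                                self_row),
                         full.names = TRUE)
  sup <- parse_pdb(readLines(lig_file))
  expect_equal(as.matrix(sup$atoms[, c("x", "y", "z")]),
               as.matrix(query$bound_ligand[, c("x", "y", "z")]),
               tolerance = 1e-3)

  sim <- as.matrix(read.delim(file.path(out, "ligand_similarity.tsv"),
                              row.names = 1))
  expect_equal(dim(sim), c(4, 4))
  expect_equal(unname(diag(sim)), rep(1, 4))
  expect_equal(sim, t(sim), ignore_attr = TRUE)
})
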