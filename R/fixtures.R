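# Synthetic ground-truth generators.
#
# A "planted pair" is two clefts sharing k_common atoms in known
# correspondence: cleft B carries a jittered, rigidly moved copy of cleft
# A's core plus its own distractors. Distractors are kept >= 6 A away from
# every core atom so they cannot join the planted correspondence under the
# 4 A proximity rule, making the ground truth provable rather than
# probabilistic. Core atoms are grouped three per synthetic residue, with a
# Calpha added per residue, so both matching stages are exercised.

STANDARD_RES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "HIS",
                  "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
                  "TRP", "TYR", "VAL")

#' Specification for a planted cleft pair
#'
#' @param k_common number of planted correspondences (>= 3).
#' @param n_noise_a,n_noise_b distractor atom counts for each cleft.
#' @param jitter_sigma isotropic coordinate noise applied to the copied core
#'   (Angstrom).
#' @param class_alphabet interaction classes the generated atoms may take.
#' @param seed integer seed; all generated artifacts are reproducible
#'   bit-for-bit from (spec, seed).
#' @return List of class \code{planted_pair_spec}.
#' @export
planted_pair_spec <- function(k_common = 20, n_noise_a = 15, n_noise_b = 15,
                              jitter_sigma = 0.2,
                              class_alphabet = ATOM_CLASSES, seed = 1) {
  if (k_common < 3) cm_input_error("planted_pair_spec: k_common must be >= 3")
  if (jitter_sigma < 0) cm_input_error("planted_pair_spec: negative jitter")
  if (!all(class_alphabet %in% ATOM_CLASSES))
    cm_input_error("planted_pair_spec: unknown class in alphabet")
  structure(list(k_common = as.integer(k_common),
                 n_noise_a = as.integer(n_noise_a),
                 n_noise_b = as.integer(n_noise_b),
                 jitter_sigma = jitter_sigma,
                 class_alphabet = class_alphabet,
                 seed = as.integer(seed)),
            class = "planted_pair_spec")
}

# Sample atom identities consistent with the packaged type table: residues
# are drawn from the standard set, atoms from that residue's side-chain and
# backbone N/C/O entries whose class lies in the alphabet. Core atoms are
# assigned one per synthetic residue: every planted atom then contributes a
# Calpha anchor, mirroring real clefts where many residues line the site
# and making the planted Calpha clique dominate the first matching stage.
sample_residue_atoms <- function(n_atoms, alphabet, res_seq_start) {
  tab <- type_table()
  n_res <- max(3L, n_atoms)
  sizes <- tabulate((seq_len(n_atoms) - 1L) %% n_res + 1L, nbins = n_res)
  rows <- list()
  res_seq <- res_seq_start
  for (s in sizes[sizes > 0]) {
    repeat {
      res <- sample(STANDARD_RES, 1)
      cand <- rbind(tab[tab$res_name == res, , drop = FALSE],
                    tab[tab$res_name == "*" &
                          tab$atom_name %in% c("N", "C", "O"), , drop = FALSE])
      # residue-specific rows shadow backbone wildcards (PRO N), and one row
      # per atom name keeps (res_seq, name) unique so typing on reload agrees
      cand <- cand[!duplicated(cand$atom_name), , drop = FALSE]
      cand <- cand[cand$class %in% alphabet, , drop = FALSE]
      if (nrow(cand) >= s) break
    }
    take <- cand[sample(nrow(cand), s), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      name = take$atom_name, res_name = res, res_seq = res_seq,
      class = take$class, stringsAsFactors = FALSE)
    res_seq <- res_seq + 1L
  }
  do.call(rbind, rows)
}

make_atom_df <- function(ident, xyz, serial_start, hetero = FALSE) {
  n <- nrow(ident)
  elem <- substr(ident$name, 1, 1)
  data.frame(serial = seq.int(serial_start, length.out = n),
             name = ident$name, alt = "",
             res_name = ident$res_name, chain = "A",
             res_seq = ident$res_seq, icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = 1, element = elem,
             is_hetero = hetero, is_hydrogen = FALSE, is_water = FALSE,
             class = ident$class, stringsAsFactors = FALSE)
}

# Calpha scaffold: one CA per residue at the residue centroid plus a fixed
# deterministic offset (keeps CAs rigid with the core).
calpha_scaffold <- function(atoms, serial_start) {
  agg <- split(seq_len(nrow(atoms)), atoms$res_seq)
  rows <- lapply(seq_along(agg), function(k) {
    idx <- agg[[k]]
    ctr <- colMeans(atom_xyz(atoms)[idx, , drop = FALSE]) + c(0.9, -0.6, 0.4)
    data.frame(serial = serial_start + k - 1L, name = "CA", alt = "",
               res_name = atoms$res_name[idx[1]], chain = "A",
               res_seq = atoms$res_seq[idx[1]], icode = "",
               x = ctr[1], y = ctr[2], z = ctr[3], occ = 1, element = "C",
               is_hetero = FALSE, is_hydrogen = FALSE, is_water = FALSE,
               class = "neutral", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Rejection-sample distractor coordinates >= exclusion from every row of
# `avoid` (matrix), inside a box around `center`.
sample_away <- function(n, avoid, center, half = 15, exclusion = 6) {
  out <- matrix(0, n, 3)
  got <- 0L
  while (got < n) {
    p <- center + stats::runif(3, -half, half)
    if (!nrow(avoid) || min(sqrt(colSums((t(avoid) - p)^2))) >= exclusion) {
      got <- got + 1L
      out[got, ] <- p
    }
  }
  out
}

#' Generate a planted cleft pair with known ground truth
#'
#' @param spec a \code{planted_pair_spec}.
#' @return List with \code{cleft_a}, \code{cleft_b} (both typed and
#'   validated), \code{truth} (data.frame of corresponding serials),
#'   \code{motion} (the rigid transform applied to B). The planted pairwise
#'   distance differences are verified at generation time against the
#'   matching thresholds; a spec whose jitter violates them is rejected.
#' @export
make_planted_cleft_pair <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  parts <- planted_core(spec)
  build_planted_pair(spec, parts)
}

planted_core <- function(spec, verify_anchor = TRUE) {
  ident <- sample_residue_atoms(spec$k_common, spec$class_alphabet, 1L)
  for (attempt in 1:50) {
    xyz <- matrix(stats::runif(3 * spec$k_common, 0, 15), ncol = 3)
    core_a <- make_atom_df(ident, xyz, 1L)
    ca_a <- calpha_scaffold(core_a, 5001L)
    if (!verify_anchor || anchor_is_safe(atom_xyz(ca_a), xyz))
      return(list(core_a = core_a, ca_a = ca_a))
  }
  cm_input_error("planted pair generation failed: no safe Calpha anchor found")
}

# Certifies the anchor: every residue bijection whose pairwise Calpha
# distances agree within the stage-1 slack (including the identity; a
# jitter margin is added) must induce a superposition that leaves every
# planted core atom within `max_disp` of its true partner -- so whichever
# maximum Calpha clique the matcher picks, all planted stage-2 nodes still
# form. Exhaustive with pruning; skipped for cores with many residues,
# where near-isometric whole-set permutations are not a practical concern.
anchor_is_safe <- function(ca_xyz, core_xyz, slack = 3.5, margin = 0.7,
                           max_disp = 3.0) {
  n <- nrow(ca_xyz)
  if (n > 8) return(TRUE)
  d <- pair_dist(ca_xyz)
  tol <- slack + margin
  ok <- TRUE
  check_perm <- function(p) {
    if (all(p == seq_len(n))) return()
    tr <- tryCatch(superpose_arun(ca_xyz[p, , drop = FALSE], ca_xyz),
                   cleftmatch_input_error = function(e) NULL)
    if (is.null(tr)) { ok <<- FALSE; return() }
    disp <- sqrt(rowSums((apply_transform(core_xyz, tr) - core_xyz)^2))
    if (max(disp) > max_disp) ok <<- FALSE
  }
  perm_rec <- function(head, rest) {
    if (!ok) return()
    m <- length(head)
    if (m >= 2) {
      # prune: prefix already violates pairwise consistency
      dh <- d[head, head, drop = FALSE]
      if (max(abs(d[seq_len(m), seq_len(m)] - dh)) > tol) return()
    }
    if (!length(rest)) { check_perm(head); return() }
    for (r in rest) perm_rec(c(head, r), setdiff(rest, r))
  }
  perm_rec(integer(), seq_len(n))
  ok
}

# Distractor atoms: grouped three per residue like the core, but under
# synthetic nonstandard residue names (unique per residue, disjoint between
# the two clefts of a pair). Nonstandard residues are substitution-
# compatible only with themselves, so distractor Calphas contribute no
# stage-1 nodes and cannot corrupt the anchoring superposition; their atoms
# are typed by the element fallback, identically at generation and reload.
distractor_atoms <- function(n_atoms, res_seq_start, prefix) {
  el <- rep(c("C", "N", "O", "S"), length.out = n_atoms)
  res_idx <- (seq_len(n_atoms) - 1L) %/% 3L
  data.frame(name = paste0(el, seq_len(n_atoms)),
             res_name = sprintf("%s%02d", prefix, res_idx + 1L),
             res_seq = res_seq_start + res_idx,
             class = vapply(el, fallback_type_single, ""),
             stringsAsFactors = FALSE)
}

build_planted_pair <- function(spec, parts) {
  core_a <- parts$core_a; ca_a <- parts$ca_a
  k <- spec$k_common

  # distractors for A
  if (spec$n_noise_a > 0) {
    ident_na <- distractor_atoms(spec$n_noise_a, 101L, "U")
    xyz_na <- sample_away(spec$n_noise_a, atom_xyz(core_a),
                          colMeans(atom_xyz(core_a)))
    noise_a <- make_atom_df(ident_na, xyz_na, 1001L)
    ca_na <- calpha_scaffold(noise_a, 6001L)
  } else noise_a <- ca_na <- NULL

  # B core: jittered copy of A's core (same identities), then rigid motion
  jitter <- matrix(stats::rnorm(3 * k, 0, spec$jitter_sigma), ncol = 3)
  core_b <- core_a
  core_b[, c("x", "y", "z")] <- atom_xyz(core_a) + jitter
  ca_b <- ca_a
  motion <- random_transform()
  core_b[, c("x", "y", "z")] <- apply_transform(atom_xyz(core_b), motion)
  ca_b[, c("x", "y", "z")] <- apply_transform(atom_xyz(ca_b), motion)

  # generation-time check of the planted consistency bounds
  da <- pair_dist(atom_xyz(core_a)); db <- pair_dist(atom_xyz(core_b))
  if (max(abs(da - db)) > 4)
    cm_input_error("planted pair generation failed: jitter breaks the 4 A consistency bound")
  dca <- pair_dist(atom_xyz(ca_a)); dcb <- pair_dist(atom_xyz(ca_b))
  if (max(abs(dca - dcb)) > 3.5)
    cm_input_error("planted pair generation failed: jitter breaks the Calpha 3.5 A bound")

  if (spec$n_noise_b > 0) {
    ident_nb <- distractor_atoms(spec$n_noise_b, 201L, "V")
    xyz_nb <- sample_away(spec$n_noise_b, atom_xyz(core_b),
                          colMeans(atom_xyz(core_b)))
    noise_b <- make_atom_df(ident_nb, xyz_nb, 2001L)
    ca_nb <- calpha_scaffold(noise_b, 7001L)
  } else noise_b <- ca_nb <- NULL

  atoms_a <- rbind(core_a, noise_a, ca_a, ca_na)
  atoms_b <- rbind(core_b, noise_b, ca_b, ca_nb)
  atoms_a <- atoms_a[order(atoms_a$serial), , drop = FALSE]
  atoms_b <- atoms_b[order(atoms_b$serial), , drop = FALSE]
  rownames(atoms_a) <- rownames(atoms_b) <- NULL

  cleft_a <- new_cleft(atoms_a, source = list(id = "planted_a"))
  cleft_b <- new_cleft(atoms_b, source = list(id = "planted_b"))
  list(cleft_a = cleft_a, cleft_b = cleft_b,
       truth = data.frame(serial_a = core_a$serial, serial_b = core_b$serial),
       motion = motion)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# A small synthetic het group: a six-membered C/N ring with two substituent
# oxygens, placed at the core centroid. Chemically minimal but gives the
# bond-perception and fingerprint code realistic rings to chew on.
synthetic_ligand <- function(center, code, serial_start = 9001L) {
  theta <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- cbind(1.39 * cos(theta), 1.39 * sin(theta), 0)
  subst <- rbind(c(2.75, 0, 0.2), c(-2.75, 0.3, -0.2))
  xyz <- sweep(rbind(ring, subst), 2, center, "+")
  el <- c("C", "N", "C", "C", "N", "C", "O", "O")
  data.frame(serial = seq.int(serial_start, length.out = 8),
             name = paste0(el, 1:8), alt = "",
             res_name = code, chain = "A", res_seq = 900L, icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
             element = el, is_hetero = TRUE, is_hydrogen = FALSE,
             is_water = FALSE, stringsAsFactors = FALSE)
}

#' Write a synthetic target dataset with planted hits
#'
#' Generates a dataset in the package's index + PDB-fragment dialect:
#' \code{n_planted} entries share the query's planted core (fresh jitter,
#' rigid motion and distractors each) and the remainder are independent
#' random clefts. Cognate-similarity coefficients are assigned cyclically on
#' the grid 0, 0.05, ..., 1. Every entry carries a synthetic ligand; planted
#' entries carry the query's ligand moved with the same rigid motion.
#'
#' @param n_entries total entries.
#' @param n_planted entries sharing the query core (<= n_entries).
#' @param query_spec a \code{planted_pair_spec} for the query and the
#'   planted copies.
#' @param seed integer master seed.
#' @param dir dataset root directory to create.
#' @return List with \code{query} (typed cleft, bound ligand attached),
#'   \code{root}, \code{index} (data.frame) and \code{planted} (pdb codes).
#' @export
make_synthetic_dataset <- function(n_entries, n_planted, query_spec, seed,
                                   dir = tempfile("icfdb_synth_")) {
  if (n_planted > n_entries)
    cm_input_error("make_synthetic_dataset: n_planted exceeds n_entries")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    cm_input_error("cannot create dataset directory '%s'", dir)

  set.seed(query_spec$seed)
  parts <- planted_core(query_spec)
  qpair <- build_planted_pair(query_spec, parts)
  query <- qpair$cleft_a
  qlig <- synthetic_ligand(colMeans(atom_xyz(parts$core_a)), "QLG")
  query$bound_ligand <- qlig
  query <- type_cleft(query)

  cognate_grid <- seq(0, 1, by = 0.05)
  pfam <- sprintf("PF%05d", ((seq_len(n_entries) - 1L) %/% 2L) + 1L)
  codes <- sprintf("s%03d", seq_len(n_entries))
  ligs <- sprintf("L%02d", ((seq_len(n_entries) - 1L) %% 60L) + 1L)

  index <- data.frame(pdb_code = codes, ligand_code = ligs, pfam_acc = pfam,
                      cognate_similarity = rep(cognate_grid,
                                               length.out = n_entries),
                      stringsAsFactors = FALSE)
  planted_codes <- codes[seq_len(n_planted)]

  for (k in seq_len(n_entries)) {
    set.seed((seed + 7L * k) %% .Machine$integer.max)
    if (k <= n_planted) {
      pair <- build_planted_pair(query_spec, parts)
      entry_cleft <- pair$cleft_b
      lig <- qlig
      lig[, c("x", "y", "z")] <- apply_transform(atom_xyz(qlig), pair$motion)
    } else {
      spec_k <- planted_pair_spec(query_spec$k_common, query_spec$n_noise_a,
                                  query_spec$n_noise_b,
                                  query_spec$jitter_sigma,
                                  query_spec$class_alphabet,
                                  seed = (seed + 7L * k) %% 1000000L)
      ind <- planted_core(spec_k, verify_anchor = FALSE)
      pair <- build_planted_pair(spec_k, ind)
      entry_cleft <- pair$cleft_b
      lig <- synthetic_ligand(
        colMeans(atom_xyz(cleft_core(entry_cleft))), ligs[k])
    }
    lig$res_name <- ligs[k]
    atoms <- entry_cleft$atoms
    write_pdb(rbind(atoms[, setdiff(names(atoms), "class")], lig),
              file = file.path(dir, sprintf("%s_%s.pdb", codes[k], ligs[k])))
  }
  utils::write.table(index, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(query = query, root = dir, index = index, planted = planted_codes)
}
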