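# Fixture builders and independent oracles shared across the suite.

# One fixed-column coordinate record.
pdb_line <- function(serial, name, res_name, res_seq, x, y, z,
                     chain = "A", het = FALSE, occ = 1, alt = " ",
                     element = substr(trimws(name), 1, 1)) {
  nm <- if (nchar(trimws(name)) < 4 && nchar(element) == 1)
    sprintf(" %-3s", trimws(name)) else sprintf("%-4s", trimws(name))
  sprintf("%-6s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, alt, res_name, chain,
          res_seq, x, y, z, occ, 0, element)
}

# A single glycine residue (N, CA, C, O) at realistic geometry.
gly_fixture <- function() {
  paste(c(
    pdb_line(1, "N", "GLY", 1, 11.104, 6.134, -6.504),
    pdb_line(2, "CA", "GLY", 1, 12.560, 6.071, -6.342),
    pdb_line(3, "C", "GLY", 1, 13.230, 7.437, -6.310),
    pdb_line(4, "O", "GLY", 1, 12.639, 8.460, -6.661),
    "END"), collapse = "\n")
}

# Two parallel 5x5 sheets of glycine-CA atoms, 8 A apart: a unique slab
# cavity for the gap-sphere detector.
sheet_fixture <- function(spacing = 3.8, gap = 8) {
  lines <- character()
  serial <- 1
  for (sheet in c(0, gap)) {
    for (i in 0:4) for (j in 0:4) {
      lines <- c(lines, pdb_line(serial, "CA", "GLY", serial,
                                 i * spacing, j * spacing, sheet))
      serial <- serial + 1
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# Brute-force maximum-clique size by subset DP over all 2^n subsets
# (n <= ~16). Independent of the package's search.
brute_force_max_clique <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 20)
  nbr <- integer(n)
  for (v in seq_len(n)) {
    nbr[v] <- sum(bitwShiftL(1L, which(adj[v, ]) - 1L))
  }
  n_masks <- bitwShiftL(1L, n)
  is_clique <- logical(n_masks)
  best <- 0L
  for (mask in 1:(n_masks - 1L)) {
    low_bit <- bitwAnd(mask, -mask)
    rest <- mask - low_bit
    if (rest == 0L) {
      is_clique[mask + 1L] <- TRUE
    } else {
      v <- as.integer(log2(low_bit)) + 1L
      is_clique[mask + 1L] <- is_clique[rest + 1L] &&
        bitwAnd(rest, nbr[v]) == rest
    }
    if (is_clique[mask + 1L]) {
      size <- sum(bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask) != 0L)
      if (size > best) best <- size
    }
  }
  best
}

random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  upper <- which(upper.tri(adj))
  on <- upper[stats::runif(length(upper)) < p]
  adj[on] <- TRUE
  adj | t(adj)
}

# Small typed cleft built directly (atoms in a box, standard identities),
# bypassing the planted-pair machinery. Deterministic given the seed.
simple_cleft <- function(n_atoms = 12, seed = 1) {
  pair <- make_planted_cleft_pair(planted_pair_spec(
    k_common = n_atoms, n_noise_a = 0, n_noise_b = 0,
    jitter_sigma = 0, seed = seed))
  type_cleft(pair$cleft_a)
}

move_cleft <- function(cleft, transform) {
  out <- cleft
  out$atoms[, c("x", "y", "z")] <- apply_transform(
    as.matrix(cleft$atoms[, c("x", "y", "z")]), transform)
  if (!is.null(out$bound_ligand)) {
    out$bound_ligand[, c("x", "y", "z")] <- apply_transform(
      as.matrix(cleft$bound_ligand[, c("x", "y", "z")]), transform)
  }
  out
}

# All printed (Z, p) rows of the published hit tables, used to validate the
# extreme-value p-value formula. One row pair (TSS 0.178 / z 1.19) appears
# twice in print with two different p-values and is therefore internally
# inconsistent; the copy not reproducible from its own z is excluded.
published_zp_rows <- function() {
  rbind(
    # query 1: atoms-in-common columns
    data.frame(z = c(3.63, 3.37, 3.24, 2.86, 2.73, 2.47, 2.60, 3.37, 2.86, 2.73),
               p = c(1.68e-2, 2.33e-2, 2.74e-2, 4.47e-2, 5.25e-2, 7.24e-2,
                     6.17e-2, 2.33e-2, 4.47e-2, 5.25e-2)),
    # query 1: Tanimoto columns
    data.frame(z = c(4.37, 4.08, 4.08, 3.55, 3.16, 3.11, 3.02, 2.97, 2.68, 2.48),
               p = c(6.51e-3, 9.44e-3, 9.44e-3, 1.86e-2, 3.04e-2, 3.24e-2,
                     3.66e-2, 3.89e-2, 5.60e-2, 7.12e-2)),
    # query 2: atoms-in-common
    data.frame(z = c(3.25, 3.59, 3.08, 3.08, 2.90, 3.08, 2.90, 3.08, 3.08, 2.90),
               p = c(2.73e-2, 1.77e-2, 3.39e-2, 3.39e-2, 4.20e-2, 3.39e-2,
                     4.20e-2, 3.39e-2, 3.39e-2, 4.20e-2)),
    # query 2: Tanimoto (excluding the self-inconsistent duplicate row)
    data.frame(z = c(3.39, 2.77, 2.69, 2.36, 2.16, 2.11, 1.33, 1.30, 1.19),
               p = c(2.29e-2, 4.95e-2, 5.49e-2, 8.29e-2, 1.05e-1, 1.12e-1,
                     2.77e-1, 2.85e-1, 3.21e-1)),
    # query 3: atoms-in-common
    data.frame(z = c(3.08, 3.46, 3.27),
               p = c(3.39e-2, 2.09e-2, 2.66e-2)),
    # query 3: Tanimoto
    data.frame(z = c(3.27, 2.89, 2.84, 2.46, 2.30, 1.55, 1.41, 1.38, 0.60,
                     0.55, 0.52),
               p = c(2.66e-2, 4.28e-2, 4.58e-2, 7.32e-2, 8.92e-2, 2.18e-1,
                     2.53e-1, 2.61e-1, 5.60e-1, 5.85e-1, 5.98e-1)),
    # case-study text values
    data.frame(z = c(4.10, 3.78, 3.98),
               p = c(9.20e-3, 1.38e-2, 1.08e-2))
  )
}

# One unit in the last printed digit of a value written as d.ddE-xx / 0.ddd.
printed_ulp <- function(p) 10^(floor(log10(p)) - 2)
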