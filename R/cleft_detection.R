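# Surfnet-style cleft detection.
#
# Gap spheres are placed between pairs of heavy atoms whose van der Waals
# surfaces are separated by a gap in [2*r_min, 2*r_max]; each sphere sits at
# the pair midpoint and is shrunk until no heavy atom penetrates it. Spheres
# that survive with radius >= r_min are clustered by overlap; clusters are
# ranked by grid-approximated volume and the atoms lining the largest
# clusters define the clefts.

#' Cleft-detection parameters
#'
#' @param r_min,r_max gap-sphere radius bounds (Angstrom; classic defaults
#'   1.0 and 4.0).
#' @param min_volume smallest cluster volume reported (Angstrom^3).
#' @param grid_spacing grid step for the union-of-spheres volume (Angstrom).
#' @param lining_pad an atom lines a cluster when within
#'   (sphere radius + lining_pad) of a sphere centre (Angstrom).
#' @return List of class \code{detect_params}.
#' @export
detect_params <- function(r_min = 1.0, r_max = 4.0, min_volume = 50,
                          grid_spacing = 0.5, lining_pad = 3.0) {
  if (r_min <= 0 || r_max <= r_min)
    cm_input_error("detect_params: need 0 < r_min < r_max")
  structure(list(r_min = r_min, r_max = r_max, min_volume = min_volume,
                 grid_spacing = grid_spacing, lining_pad = lining_pad),
            class = "detect_params")
}

#' Place one gap sphere between a pair of atoms
#'
#' The sphere is centred at the midpoint of the pair with initial radius
#' \code{min(r_max, half the gap between the van der Waals surfaces)} and is
#' shrunk until no neighbour's van der Waals sphere penetrates it. Rejected
#' (NULL) when the final radius falls below \code{r_min}.
#'
#' @param a,b single-row atom data.frames (distinct atoms).
#' @param neighbors atom data.frame of surrounding heavy atoms.
#' @param params a \code{detect_params}.
#' @return List with \code{center} and \code{radius}, or NULL.
#' @export
place_gap_sphere <- function(a, b, neighbors, params = detect_params()) {
  pa <- as.numeric(a[1, c("x", "y", "z")])
  pb <- as.numeric(b[1, c("x", "y", "z")])
  d <- sqrt(sum((pa - pb)^2))
  if (d == 0) cm_input_error("place_gap_sphere: coincident atoms")
  gap <- d - vdw_radius(a$element[1]) - vdw_radius(b$element[1])
  r <- min(params$r_max, gap / 2)
  if (r < params$r_min) return(NULL)
  center <- (pa + pb) / 2
  if (!is.null(neighbors) && nrow(neighbors)) {
    dn <- sqrt(colSums((t(atom_xyz(neighbors)) - center)^2)) -
      vdw_radius(neighbors$element)
    r <- min(r, dn)
  }
  if (r < params$r_min) return(NULL)
  list(center = center, radius = r)
}

#' Detect the largest surface clefts of a structure
#'
#' Returns up to \code{max_clefts} clefts ordered by cluster volume
#' descending (ties by lining-atom count, then by first atom serial). Each
#' cleft's atoms are the cluster's lining atoms plus the Calpha of every
#' represented residue. Restricting to one chain avoids clefts at
#' inter-chain interfaces.
#'
#' @param structure a \code{cleft_structure}.
#' @param chain optional chain identifier; only that chain's atoms are used.
#' @param params a \code{detect_params}.
#' @param max_clefts maximum number of clefts returned (default 3).
#' @return List of \code{cleft} objects (possibly empty, with a warning).
#' @export
detect_clefts <- function(structure, chain = NULL, params = detect_params(),
                          max_clefts = 3) {
  atoms <- structure$atoms
  atoms <- atoms[!atoms$is_hydrogen & !atoms$is_water, , drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) < 2) {
    cm_warn("no clefts: fewer than 2 heavy atoms available")
    return(list())
  }
  xyz <- atom_xyz(atoms)
  vdw <- vdw_radius(atoms$element)
  n <- nrow(xyz)

  # candidate pairs: vdW-surface gap within [2*r_min, 2*r_max]
  centers <- NULL; radii <- numeric()
  max_pair_d <- 2 * params$r_max + 2 * max(vdw)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    d <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
    gap <- d - vdw[i] - vdw[js]
    cand <- js[gap >= 2 * params$r_min & gap <= 2 * params$r_max & d <= max_pair_d]
    for (j in cand) {
      center <- (xyz[i, ] + xyz[j, ]) / 2
      r <- min(params$r_max, (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) -
                                vdw[i] - vdw[j]) / 2)
      dn <- sqrt(colSums((t(xyz) - center)^2)) - vdw
      r <- min(r, dn)
      if (r >= params$r_min) {
        centers <- rbind(centers, center)
        radii <- c(radii, r)
      }
    }
  }
  if (is.null(centers) || !nrow(centers)) {
    cm_warn("no clefts: no gap sphere above minimum radius")
    return(list())
  }

  # cluster by sphere overlap (connected components of the overlap graph)
  comp <- overlap_components(centers, radii)
  clusters <- split(seq_along(radii), comp)

  info <- lapply(clusters, function(idx) {
    vol <- sphere_union_volume(centers[idx, , drop = FALSE], radii[idx],
                               params$grid_spacing)
    lin <- lining_atoms(xyz, centers[idx, , drop = FALSE], radii[idx],
                        params$lining_pad)
    list(idx = idx, volume = vol, lining = lin)
  })
  info <- Filter(function(ci) ci$volume >= params$min_volume && length(ci$lining) > 0,
                 info)
  if (!length(info)) {
    cm_warn("no clefts: no cluster above minimum volume")
    return(list())
  }
  ord <- order(-vapply(info, function(ci) ci$volume, 0),
               -vapply(info, function(ci) length(ci$lining), 0L),
               vapply(info, function(ci) min(atoms$serial[ci$lining]), 0L))
  info <- info[ord][seq_len(min(max_clefts, length(info)))]

  out <- list()
  for (k in seq_along(info)) {
    ci <- info[[k]]
    cleft <- tryCatch(
      new_cleft(atoms[ci$lining, , drop = FALSE],
                source = list(id = structure$id, rank = k,
                              volume = ci$volume,
                              n_spheres = length(ci$idx)),
                structure = structure),
      cleftmatch_input_error = function(e) {
        cm_warn("cleft %d rejected: %s", k, conditionMessage(e))
        NULL
      })
    if (!is.null(cleft)) out[[length(out) + 1]] <- cleft
  }
  out
}

overlap_components <- function(centers, radii) {
  m <- length(radii)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- pair_dist(centers)
  touch <- d < outer(radii, radii, "+")
  for (i in seq_len(m - 1)) for (j in which(touch[i, (i + 1):m]) + i) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(m), find, 0L)
}

sphere_union_volume <- function(centers, radii, spacing) {
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  inside <- 0L
  # slice along x to bound memory
  for (x in gx) {
    pts <- cbind(x, rep(gy, times = length(gz)), rep(gz, each = length(gy)))
    hit <- rep(FALSE, nrow(pts))
    for (s in seq_along(radii)) {
      hit <- hit | (colSums((t(pts) - centers[s, ])^2) <= radii[s]^2)
    }
    inside <- inside + sum(hit)
  }
  inside * spacing^3
}

lining_atoms <- function(xyz, centers, radii, pad) {
  d <- cross_dist(xyz, centers)
  which(rowSums(sweep(d, 2, radii + pad) <= 0) > 0)
}

#' Define a cleft from a bound ligand or residue
#'
#' The cleft consists of every atom of every residue having at least one
#' heavy atom within \code{cutoff} of any heavy atom of the ligand, plus the
#' Calpha atoms of those residues. The ligand's atoms populate
#' \code{bound_ligand}.
#'
#' @param structure a \code{cleft_structure}.
#' @param ligand a \code{residue_id}, or a full/partial RESNUMCA string
#'   (a partial id must resolve to exactly one residue).
#' @param cutoff contact distance, heavy atom to heavy atom (Angstrom).
#' @return A validated \code{cleft} with \code{bound_ligand} set.
#' @export
cleft_from_ligand <- function(structure, ligand, cutoff = 4.5) {
  atoms <- structure$atoms
  atoms <- atoms[!atoms$is_hydrogen & !atoms$is_water, , drop = FALSE]
  rid <- resolve_residue(structure, ligand)
  lig_rows <- atoms$res_name == rid$res_code & atoms$res_seq == rid$number &
    (!nzchar(rid$chain) | atoms$chain == rid$chain)
  lig <- atoms[lig_rows, , drop = FALSE]
  if (!nrow(lig))
    cm_input_error("ligand '%s' resolves to no heavy atoms",
                   format_residue_id(rid))
  rest <- atoms[!lig_rows, , drop = FALSE]
  if (!nrow(rest)) cm_input_error("cleft smaller than 4 atoms: no residues near ligand")
  d <- cross_dist(atom_xyz(rest), atom_xyz(lig))
  near <- apply(d, 1, min) <= cutoff
  res_key <- paste(rest$chain, rest$res_seq, rest$icode, rest$res_name)
  keep_res <- unique(res_key[near])
  sel <- rest[res_key %in% keep_res, , drop = FALSE]
  if (nrow(sel) < 4)
    cm_input_error("cleft smaller than 4 atoms: only %d atom(s) within %.1f A of %s",
                   nrow(sel), cutoff, format_residue_id(rid))
  new_cleft(sel,
            source = list(id = structure$id,
                          ligand = format_residue_id(rid)),
            bound_ligand = lig, structure = structure)
}

resolve_residue <- function(structure, ligand) {
  if (inherits(ligand, "residue_id")) return(ligand)
  full <- tryCatch(parse_residue_id(ligand), cleftmatch_input_error = function(e) NULL)
  if (!is.null(full)) {
    # full id: look it up directly (a blank chain matches a unique residue
    # on any chain, since minimal cleft files often drop the chain column)
    res <- residue_table(structure$atoms)
    hit <- res$res_name == full$res_code & res$res_seq == full$number &
      (!nzchar(full$chain) | res$chain == full$chain)
    if (sum(hit) == 1) {
      k <- which(hit)
      return(structure(list(res_code = res$res_name[k], number = res$res_seq[k],
                            chain = res$chain[k], alt = ""),
                       class = "residue_id"))
    }
    if (sum(hit) > 1)
      cm_input_error("ambiguous ligand id '%s': candidates %s", ligand,
                     paste(residue_canonical_id(res[hit, , drop = FALSE]),
                           collapse = ", "))
  }
  matches <- find_residue_matches(structure, ligand)
  if (length(matches) == 1) return(matches[[1]])
  if (!length(matches))
    cm_input_error("unresolved ligand id '%s': no matching residue", ligand)
  cm_input_error("ambiguous ligand id '%s': candidates %s", ligand,
                 paste(vapply(matches, format_residue_id, ""), collapse = ", "))
}
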