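# Interaction-class atom typing.
#
# Every heavy atom is assigned one of eight interaction classes
# (hydrophilic, acceptor, donor, hydrophobic, aromatic, neutral,
# neutral-donor, neutral-acceptor). Class equality is the node-compatibility
# rule of the all-atom matching stage. Standard residues are typed from a
# packaged lookup table; het-group atoms fall back to element + bond-context
# rules (bonds inferred from covalent radii).

ATOM_CLASSES <- c("hydrophilic", "acceptor", "donor", "hydrophobic",
                  "aromatic", "neutral", "neutral-donor", "neutral-acceptor")

type_table_env <- new.env(parent = emptyenv())

type_table <- function() {
  if (is.null(type_table_env$tab)) {
    tab <- utils::read.delim(extdata("sobolev_atom_types.tsv"),
                             stringsAsFactors = FALSE)
    stopifnot(all(tab$class %in% ATOM_CLASSES))
    type_table_env$tab <- tab
    type_table_env$key <- paste(tab$res_name, tab$atom_name)
  }
  type_table_env$tab
}

#' Assign the interaction class of a single standard-residue atom
#'
#' Looks up the packaged (residue, atom-name) class table; backbone atoms are
#' covered by wildcard rows and selenomethionine is typed as methionine.
#' Het-group atoms are typed with bond context by \code{type_cleft}; this
#' lookup signals an error when no table entry applies and no element is
#' known.
#'
#' @param res_name 3-letter residue code.
#' @param atom_name PDB atom name.
#' @param element element symbol (used for the het fallback).
#' @return One of the eight class labels.
#' @export
assign_atom_type <- function(res_name, atom_name, element = "") {
  tab <- type_table()
  key <- type_table_env$key
  res <- toupper(trimws(res_name)); atm <- toupper(trimws(atom_name))
  hit <- match(paste(res, atm), key)
  if (is.na(hit)) hit <- match(paste("*", atm), key)
  if (!is.na(hit)) return(tab$class[hit])
  fallback_type_single(toupper(element))
}

# Context-free element fallback (used when bond context is unavailable).
fallback_type_single <- function(element) {
  if (!nzchar(element)) cm_input_error("untypable atom: unknown element")
  switch(element,
         C = "hydrophobic",
         N = "donor",
         O = "hydrophilic",
         S = "neutral", P = "neutral", SE = "neutral",
         F = "hydrophobic", CL = "hydrophobic", BR = "hydrophobic",
         I = "hydrophobic",
         "hydrophilic") # metals and anything else polarizing
}

# Bond-context typing of a het group (one residue's atoms at a time).
#   C bonded only to C         -> hydrophobic
#   C in a 5/6-ring of sp2-ish atoms -> aromatic
#   other C                    -> neutral
#   N with H capacity (<=2 heavy neighbours) -> donor, else neutral-donor
#   terminal O on an acid/ester-like centre  -> acceptor
#   terminal O otherwise (hydroxyl-like)     -> hydrophilic
#   bridging O (ether/ester)   -> neutral-acceptor
#   S, P, Se                   -> neutral; halogens hydrophobic; metals hydrophilic
type_het_group <- function(atoms) {
  n <- nrow(atoms)
  graph <- infer_bonds(atoms)
  adj <- graph$adjacency
  deg <- rowSums(adj)
  el <- toupper(atoms$element)
  ring <- ring_membership(adj, deg)
  cls <- character(n)
  for (k in seq_len(n)) {
    nb <- which(adj[k, ])
    cls[k] <- switch(el[k],
      C = {
        if (ring[k]) "aromatic"
        else if (length(nb) == 0 || all(el[nb] == "C")) "hydrophobic"
        else "neutral"
      },
      N = if (deg[k] <= 2) "donor" else "neutral-donor",
      O = {
        if (deg[k] >= 2) "neutral-acceptor"
        else if (length(nb) == 1 &&
                 el[nb] %in% c("C", "P", "S") &&
                 sum(el[which(adj[nb, ])] == "O") >= 2) "acceptor"
        else "hydrophilic"
      },
      S = "neutral", P = "neutral", SE = "neutral",
      F = "hydrophobic", CL = "hydrophobic", BR = "hydrophobic",
      I = "hydrophobic",
      "hydrophilic")
  }
  cls
}

# Flags atoms belonging to a 5- or 6-cycle in which every member has at most
# three heavy neighbours (a cheap sp2/aromatic proxy; no planarity test).
ring_membership <- function(adj, deg) {
  n <- nrow(adj)
  member <- rep(FALSE, n)
  sp2 <- deg <= 3
  if (n < 5) return(member)
  for (len in c(5L, 6L)) {
    for (start in seq_len(n)) {
      if (!sp2[start]) next
      member <- member | find_cycle_from(adj, sp2, start, len)
    }
  }
  member
}

find_cycle_from <- function(adj, ok, start, len) {
  n <- nrow(adj)
  hit <- rep(FALSE, n)
  path <- integer(len)
  recurse <- function(v, depth, used) {
    path[depth] <<- v
    if (depth == len) {
      if (adj[v, start]) hit[path] <<- TRUE
      return()
    }
    for (w in which(adj[v, ])) {
      if (!ok[w] || used[w] || w < start) next
      used[w] <- TRUE
      recurse(w, depth + 1L, used)
      used[w] <- FALSE
    }
  }
  used <- rep(FALSE, n)
  used[start] <- TRUE
  recurse(start, 1L, used)
  hit
}

#' Type every atom of a cleft
#'
#' Adds a \code{class} column to the cleft's atoms (and bound ligand, if any).
#' Standard-residue atoms use the packaged table; het-group atoms are typed
#' per residue with distance-inferred bond context. Untypable atoms are
#' dropped with a warning; typing is idempotent.
#'
#' @param cleft a validated \code{cleft}.
#' @return The cleft with all atoms labelled.
#' @export
type_cleft <- function(cleft) {
  cleft$atoms <- type_atoms(cleft$atoms)
  if (!is.null(cleft$bound_ligand))
    cleft$bound_ligand <- type_atoms(cleft$bound_ligand)
  if (nrow(cleft$atoms) < 4)
    cm_input_error("fewer than 4 typable atoms in cleft")
  validate_cleft(cleft)
  cleft
}

type_atoms <- function(atoms) {
  n <- nrow(atoms)
  cls <- if (is.null(atoms$class)) rep(NA_character_, n) else atoms$class
  todo <- is.na(cls)
  if (!any(todo)) { atoms$class <- cls; return(atoms) }

  std <- todo & !atoms$is_hetero
  for (k in which(std)) {
    cls[k] <- tryCatch(assign_atom_type(atoms$res_name[k], atoms$name[k],
                                        atoms$element[k]),
                       cleftmatch_input_error = function(e) NA_character_)
  }
  het <- todo & atoms$is_hetero
  if (any(het)) {
    key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$res_name)
    for (grp in unique(key[het])) {
      idx <- which(het & key == grp)
      known <- nzchar(atoms$element[idx])
      if (any(known))
        cls[idx[known]] <- type_het_group(atoms[idx[known], , drop = FALSE])
    }
  }
  bad <- todo & is.na(cls)
  if (any(bad)) {
    cm_warn("dropping %d untypable atom(s)", sum(bad))
    atoms <- atoms[!bad, , drop = FALSE]
    cls <- cls[!bad]
  }
  atoms$class <- cls
  rownames(atoms) <- NULL
  atoms
}

is_typed <- function(cleft) {
  !is.null(cleft$atoms$class) && !anyNA(cleft$atoms$class)
}
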