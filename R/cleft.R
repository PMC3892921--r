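# The cleft container: a set of typed heavy atoms representing a candidate
# binding site. Two constraints are enforced on every cleft:
#   * it contains four or more atoms;
#   * every residue contributing an atom has its Calpha atom present
#     (the Calpha set anchors the first, residue-level matching stage).

#' Construct a validated cleft
#'
#' Hydrogens and waters are removed. When a \code{structure} is supplied,
#' missing Calpha atoms of represented residues are pulled from it; otherwise
#' every (non-het) residue must already carry its Calpha.
#'
#' @param atoms atom data.frame of heavy cleft atoms (may include Calphas).
#' @param source provenance list (structure id, ligand id or cleft rank, ...).
#' @param bound_ligand optional atom data.frame of the bound ligand.
#' @param structure optional \code{cleft_structure} used to complete Calphas.
#' @return Object of class \code{cleft}: list with \code{atoms} (all heavy
#'   atoms incl. Calphas), \code{source}, \code{bound_ligand}.
#' @export
new_cleft <- function(atoms, source = list(), bound_ligand = NULL,
                      structure = NULL) {
  atoms <- atoms[!atoms$is_hydrogen & !atoms$is_water, , drop = FALSE]
  if (!is.null(bound_ligand)) {
    bound_ligand <- bound_ligand[!bound_ligand$is_hydrogen &
                                   !bound_ligand$is_water, , drop = FALSE]
    if (!nrow(bound_ligand)) bound_ligand <- NULL
  }
  if (!is.null(structure)) atoms <- add_calpha(atoms, structure)
  cleft <- structure(list(atoms = atoms, source = source,
                          bound_ligand = bound_ligand),
                     class = "cleft")
  validate_cleft(cleft)
  cleft
}

add_calpha <- function(atoms, structure) {
  sa <- structure$atoms
  res_key <- function(a) paste(a$chain, a$res_seq, a$icode, a$res_name, sep = "|")
  prot <- atoms[!atoms$is_hetero, , drop = FALSE]
  need <- unique(res_key(prot))
  have_ca <- res_key(atoms)[atoms$name == "CA" & !atoms$is_hetero]
  missing <- setdiff(need, have_ca)
  if (length(missing)) {
    cand <- sa[sa$name == "CA" & !sa$is_hetero & !sa$is_hydrogen &
                 res_key(sa) %in% missing, , drop = FALSE]
    atoms <- rbind(atoms, cand)
    atoms <- atoms[!duplicated(paste(res_key(atoms), atoms$name)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  atoms
}

#' Validate a cleft's structural constraints
#'
#' @param cleft a \code{cleft}.
#' @return The cleft, invisibly; signals an input error on violation.
#' @export
validate_cleft <- function(cleft) {
  atoms <- cleft$atoms
  if (is.null(atoms) || nrow(atoms) < 4)
    cm_input_error("invalid cleft: must contain four or more atoms (has %d)",
                   if (is.null(atoms)) 0L else nrow(atoms))
  if (any(atoms$is_hydrogen))
    cm_runtime_error("invalid cleft: contains hydrogen atoms")
  prot <- atoms[!atoms$is_hetero, , drop = FALSE]
  if (nrow(prot)) {
    res_key <- paste(prot$chain, prot$res_seq, prot$icode, prot$res_name)
    ca_key <- res_key[prot$name == "CA"]
    missing <- setdiff(unique(res_key), ca_key)
    if (length(missing))
      cm_input_error("invalid cleft: %d residue(s) lack a Calpha atom (%s)",
                     length(missing), paste(missing[seq_len(min(3, length(missing)))],
                                            collapse = "; "))
  }
  invisible(cleft)
}

# Calpha atoms (protein only) -- the stage-1 anchor set.
cleft_calpha <- function(cleft) {
  cleft$atoms[cleft$atoms$name == "CA" & !cleft$atoms$is_hetero, , drop = FALSE]
}

# Atoms that take part in the all-atom matching stage and in the similarity
# counts N_A/N_B: everything except the (artificially included) Calphas.
cleft_core <- function(cleft) {
  cleft$atoms[!(cleft$atoms$name == "CA" & !cleft$atoms$is_hetero), , drop = FALSE]
}

#' Number of atoms a cleft contributes to similarity measurement
#'
#' Calpha atoms anchor the residue-level stage only and are excluded.
#' @param cleft a \code{cleft}.
#' @return Integer atom count.
#' @export
cleft_size <- function(cleft) nrow(cleft_core(cleft))

#' @export
print.cleft <- function(x, ...) {
  src <- paste(unlist(x$source), collapse = " ")
  cat(sprintf("<cleft%s: %d atoms (%d Calpha), %s ligand>\n",
              if (nzchar(src)) paste0(" ", src) else "",
              nrow(x$atoms), nrow(cleft_calpha(x)),
              if (is.null(x$bound_ligand)) "no" else
                x$bound_ligand$res_name[1]))
  invisible(x)
}

#' Build a cleft from a parsed cleft file
#'
#' A cleft file is a plain PDB fragment: ATOM records define the site's
#' residues (Calphas included) and HETATM records, if any, a bound ligand.
#'
#' @param structure a \code{cleft_structure}.
#' @param source provenance list.
#' @return A validated \code{cleft}.
#' @export
cleft_from_structure <- function(structure, source = list(id = structure$id)) {
  atoms <- structure$atoms
  atoms <- atoms[!atoms$is_hydrogen & !atoms$is_water, , drop = FALSE]
  lig <- atoms[atoms$is_hetero, , drop = FALSE]
  prot <- atoms[!atoms$is_hetero, , drop = FALSE]
  if (!nrow(prot)) cm_input_error("cleft file '%s' has no ATOM records",
                                  structure$id)
  new_cleft(prot, source = source,
            bound_ligand = if (nrow(lig)) lig else NULL)
}

#' Remove residues from a cleft
#'
#' Removes every atom (including the Calpha) of each named residue and
#' re-validates the result. Residues not present are ignored.
#'
#' @param cleft a \code{cleft}.
#' @param residues list of \code{residue_id} objects (or RESNUMCA strings).
#' @return The reduced, validated \code{cleft}.
#' @export
deselect_residues <- function(cleft, residues) {
  if (inherits(residues, "residue_id")) residues <- list(residues)
  rids <- lapply(residues, function(r)
    if (is.character(r)) parse_residue_id(r) else r)
  atoms <- cleft$atoms
  drop <- rep(FALSE, nrow(atoms))
  for (r in rids) {
    drop <- drop | (atoms$res_name == r$res_code &
                      atoms$res_seq == r$number &
                      atoms$chain == r$chain)
  }
  out <- cleft
  out$atoms <- atoms[!drop, , drop = FALSE]
  validate_cleft(out)
  out
}
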