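# Structure and cleft file I/O.
#
# Internal atom representation: a data.frame with one row per atom and columns
#   serial, name, alt, res_name, chain, res_seq, icode, x, y, z, occ,
#   element, is_hetero, is_hydrogen, is_water
# plus, after typing, a 'class' column with one of the eight interaction
# classes. Only heavy atoms take part in any downstream computation.

TWO_LETTER_METALS <- c("FE", "ZN", "MG", "MN", "CU", "NI", "CO", "MO", "CD",
                       "HG", "PT", "AU", "AG", "AL", "LI", "RB", "CS", "SR",
                       "BA", "PB")

infer_element <- function(name, res_name, is_hetero) {
  nm <- toupper(trimws(name))
  stripped <- gsub("[^A-Z]", "", nm)
  rn <- toupper(trimws(res_name))
  out <- character(length(nm))
  for (k in seq_along(nm)) {
    s <- stripped[k]
    if (!nzchar(s)) { out[k] <- ""; next }
    if (is_hetero[k] && rn[k] == nm[k] &&
        s %in% c(TWO_LETTER_METALS, "NA", "CA", "K", "CL", "BR", "I", "F", "SE")) {
      # monoatomic het group named after its element (ions: CA, ZN, CL, ...)
      out[k] <- s
    } else if (is_hetero[k] && s %in% TWO_LETTER_METALS) {
      out[k] <- s
    } else if (s %in% c("CL", "BR", "SE") && !is_hetero[k] && rn[k] == "MSE") {
      out[k] <- s
    } else {
      out[k] <- substr(s, 1, 1)
    }
  }
  out
}

#' Parse a PDB-format string into a structure
#'
#' Reads fixed-column ATOM/HETATM records (first MODEL only). Hydrogens and
#' waters are retained but flagged; at most one alternate-location variant is
#' kept per atom (highest occupancy, ties broken by alphabetical alt code).
#' Malformed coordinate records are skipped with a warning. Column extraction
#' is delegated to \code{bio3d::read.pdb}.
#'
#' @param text PDB-format character string (records separated by newlines).
#' @param id identifier stored on the returned structure.
#' @return An object of class \code{cleft_structure}: a list with elements
#'   \code{id} and \code{atoms} (data.frame as described above).
#' @export
parse_pdb <- function(text, id = "structure") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("\r$", "", lines)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  is_coord <- trimws(rec) %in% c("ATOM", "HETATM")
  coord <- lines[is_coord]
  if (!length(coord)) cm_input_error("empty structure: no ATOM/HETATM records")
  bad <- nchar(coord) < 54
  if (any(bad)) {
    for (b in coord[bad]) cm_warn("skipping malformed PDB record: '%s'", b)
    coord <- coord[!bad]
  }
  if (!length(coord)) cm_input_error("empty structure: no parsable coordinate records")

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(c(coord, "END"), tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  atoms <- data.frame(
    serial   = as.integer(at$eleno),
    name     = trimws(blank(at$elety)),
    alt      = blank(at$alt),
    res_name = trimws(blank(at$resid)),
    chain    = blank(at$chain),
    res_seq  = as.integer(at$resno),
    icode    = blank(at$insert),
    x = at$x, y = at$y, z = at$z,
    occ      = ifelse(is.na(at$o), 1, at$o),
    element  = toupper(trimws(blank(at$elesy))),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )

  ok <- is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z) &
    !is.na(atoms$res_seq)
  if (any(!ok)) {
    cm_warn("skipping %d record(s) with missing coordinates or residue number",
            sum(!ok))
    atoms <- atoms[ok, , drop = FALSE]
  }
  if (!nrow(atoms)) cm_input_error("empty structure: no parsable coordinate records")

  miss <- !nzchar(atoms$element)
  if (any(miss)) {
    atoms$element[miss] <- infer_element(atoms$name[miss], atoms$res_name[miss],
                                         atoms$is_hetero[miss])
  }
  untyped <- !nzchar(atoms$element)
  if (any(untyped)) {
    cm_warn("dropping %d record(s) with no inferable element", sum(untyped))
    atoms <- atoms[!untyped, , drop = FALSE]
  }

  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$is_water <- atoms$res_name %in% c("HOH", "WAT", "DOD")

  # Alternate locations: keep highest occupancy, ties by alphabetical alt.
  key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$res_name,
               atoms$name, sep = "|")
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(list(id = id, atoms = atoms), class = "cleft_structure")
}

#' Read a PDB file from disk
#'
#' @param path file path; the file stem becomes the structure id.
#' @inherit parse_pdb return
#' @export
read_pdb_file <- function(path) {
  if (!file.exists(path)) cm_input_error("PDB file not found: '%s'", path)
  parse_pdb(readLines(path, warn = FALSE),
            id = sub("\\.[^.]*$", "", basename(path)))
}

#' @export
print.cleft_structure <- function(x, ...) {
  cat(sprintf("<structure %s: %d atoms, %d residues>\n", x$id, nrow(x$atoms),
              nrow(residue_table(x$atoms))))
  invisible(x)
}

# --- RESNUMCA residue identifiers --------------------------------------------

#' Parse a RESNUMCA residue identifier
#'
#' The RESNUMCA format concatenates the three-letter residue code, the residue
#' number, the chain character and the alternate-location character, with a
#' dash standing in for a blank chain or alt code (e.g. \code{"BTN300--"},
#' \code{"ASN94A-"}). Trailing chain/alt characters may be omitted.
#'
#' @param s identifier string.
#' @return An object of class \code{residue_id} with fields \code{res_code},
#'   \code{number}, \code{chain}, \code{alt} (blank stored as \code{""}).
#' @export
parse_residue_id <- function(s) {
  if (!is.character(s) || length(s) != 1)
    cm_input_error("bad residue id: expected a single string")
  m <- regmatches(s, regexec("^(.{3})([0-9]+)([^0-9]?)([^0-9]?)$", s))[[1]]
  if (!length(m))
    cm_input_error("bad residue id '%s': expected RESNUMCA format", s)
  code <- toupper(trimws(m[2]))
  if (!nzchar(code))
    cm_input_error("bad residue id '%s': empty residue code", s)
  chain <- m[4]; alt <- m[5]
  if (chain == "-") chain <- ""
  if (alt == "-") alt <- ""
  structure(list(res_code = code, number = as.integer(m[3]),
                 chain = chain, alt = alt),
            class = "residue_id")
}

#' Format a residue identifier in canonical RESNUMCA form
#'
#' @param rid a \code{residue_id}.
#' @return Canonical string with dashes for blank chain/alt;
#'   \code{format_residue_id(parse_residue_id(s)) == s} for canonical strings.
#' @export
format_residue_id <- function(rid) {
  dash <- function(v) if (is.null(v) || !nzchar(v)) "-" else v
  sprintf("%s%d%s%s", rid$res_code, rid$number, dash(rid$chain), dash(rid$alt))
}

#' @export
print.residue_id <- function(x, ...) {
  cat(format_residue_id(x), "\n")
  invisible(x)
}

# Unique residues of an atom table, in file order.
residue_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$res_name, sep = "|")
  first <- !duplicated(key)
  data.frame(res_name = atoms$res_name[first], res_seq = atoms$res_seq[first],
             chain = atoms$chain[first], icode = atoms$icode[first],
             is_hetero = atoms$is_hetero[first],
             stringsAsFactors = FALSE)
}

residue_canonical_id <- function(res) {
  dash <- function(v) ifelse(nzchar(v), v, "-")
  # alt is an atom-level attribute; residue ids are formatted with a blank alt.
  sprintf("%s%d%s-", res$res_name, res$res_seq, dash(res$chain))
}

#' Find residues matching a partial RESNUMCA identifier
#'
#' Pattern matching is by prefix on the canonical id (e.g. a bare residue code
#' such as \code{"AMP"} matches every AMP het group). Insertion codes are not
#' representable in RESNUMCA and are ignored by matching.
#'
#' @param x a \code{cleft_structure} (or atom data.frame).
#' @param partial prefix of a RESNUMCA id.
#' @return List of \code{residue_id} objects, in file order (empty on no match).
#' @export
find_residue_matches <- function(x, partial) {
  atoms <- if (inherits(x, "cleft_structure")) x$atoms else x
  res <- residue_table(atoms)
  ids <- residue_canonical_id(res)
  hit <- startsWith(ids, toupper(trimws(partial)))
  lapply(which(hit), function(k) {
    structure(list(res_code = res$res_name[k], number = res$res_seq[k],
                   chain = res$chain[k], alt = ""),
              class = "residue_id")
  })
}

# --- Writing -----------------------------------------------------------------

fmt_atom_name <- function(name, element) {
  out <- character(length(name))
  for (k in seq_along(name)) {
    if (nchar(name[k]) < 4 && nchar(element[k]) == 1) {
      out[k] <- sprintf(" %-3s", name[k])
    } else {
      out[k] <- sprintf("%-4s", name[k])
    }
  }
  out
}

#' Write atoms as fixed-column PDB records
#'
#' @param atoms atom data.frame (as produced by \code{parse_pdb}).
#' @param transform optional rigid \code{cleft_transform} applied to the
#'   coordinates before writing.
#' @param file optional output path; when given the text is also written there.
#' @return PDB-format string (invisibly when \code{file} is given).
#' @export
write_pdb <- function(atoms, transform = NULL, file = NULL) {
  if (inherits(atoms, "cleft_structure")) atoms <- atoms$atoms
  if (!nrow(atoms)) cm_input_error("write_pdb: no atoms to write")
  xyz <- atom_xyz(atoms)
  if (!is.null(transform)) xyz <- apply_transform(xyz, transform)
  lines <- sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(atoms$is_hetero, "HETATM", "ATOM"),
                   atoms$serial %% 100000L,
                   fmt_atom_name(atoms$name, atoms$element),
                   ifelse(nzchar(atoms$alt), atoms$alt, " "),
                   atoms$res_name,
                   ifelse(nzchar(atoms$chain), atoms$chain, " "),
                   atoms$res_seq %% 10000L,
                   ifelse(nzchar(atoms$icode), atoms$icode, " "),
                   xyz[, 1], xyz[, 2], xyz[, 3],
                   atoms$occ, 0,
                   atoms$element)
  out <- paste(c(lines, "END"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
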