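#' Read a PDB file (single structure or multi-MODEL trajectory)
#'
#' Parses fixed-column (v3.3) ATOM/HETATM records.  With
#' `model_policy = "first"` the first MODEL (or the whole file when no
#' MODEL records are present) is returned as a [molecular_system()]; with
#' `model_policy = "all"` every MODEL becomes one frame of a
#' [trajectory()].  Coordinates are in Angstrom.  Atoms get placeholder
#' topology (charge 0, epsilon 0, element-default radius and mass) until
#' [read_topology()] fills them in; all atoms start in the receptor group.
#'
#' altLoc codes other than blank or 'A' are rejected: alternate locations
#' have no meaning for the single-conformer analyses here and silently
#' picking one would be nondeterministic across files.
#'
#' @param path PDB file path.
#' @param model_policy `"first"` or `"all"`.
#' @param times optional frame times (ns) when reading a trajectory;
#'   defaults to 0, 1, 2, ...
#' @return A `molecular_system`, or a `trajectory` when
#'   `model_policy = "all"` (even for a single model).
#' @seealso [write_pdb()], [read_topology()]
#' @export
read_pdb <- function(path, model_policy = c("first", "all"), times = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) .stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)

  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    substr(rec, 1, 4) %in% c("ATOM") | substr(rec, 1, 6) == "HETATM"
  is_model_open <- startsWith(lines, "MODEL")
  is_model_close <- startsWith(lines, "ENDMDL")

  ## assign a model id to every atom line
  model_id <- cumsum(is_model_open)
  has_models <- any(is_model_open)
  atom_lines <- which(is_atom)
  if (!length(atom_lines)) .stopf("no ATOM/HETATM records in %s", path)
  ## atom lines after ENDMDL but before next MODEL would be orphans
  closed <- cumsum(is_model_close)
  if (has_models && any(model_id[atom_lines] == closed[atom_lines]))
    .stopf("ATOM record outside MODEL/ENDMDL at line %d",
           atom_lines[model_id[atom_lines] == closed[atom_lines]][1L])

  parse_block <- function(idx) {
    ln <- lines[idx]
    num_field <- function(s, what, lineno) {
      v <- suppressWarnings(as.numeric(s))
      bad <- is.na(v) & nzchar(trimws(s))
      bad <- bad | !nzchar(trimws(s))
      if (any(bad))
        .stopf("malformed %s field in PDB record at line %d", what, lineno[bad][1L])
      v
    }
    if (any(nchar(ln) < 54))
      .stopf("truncated ATOM/HETATM record at line %d", idx[nchar(ln) < 54][1L])
    altloc <- substr(ln, 17, 17)
    if (any(!altloc %in% c(" ", "A")))
      .stopf("unsupported altLoc '%s' at line %d",
             altloc[!altloc %in% c(" ", "A")][1L],
             idx[!altloc %in% c(" ", "A")][1L])
    name <- trimws(substr(ln, 13, 16))
    element <- trimws(substr(ln, 77, 78))
    ## fall back on the first letter of the atom name when the element
    ## column is absent (common in minimal PDBs)
    element[!nzchar(element)] <-
      sub("^[0-9]*([A-Za-z]).*$", "\\1", name[!nzchar(element)])
    data.frame(
      serial = as.integer(num_field(substr(ln, 7, 11), "serial", idx)),
      name = name,
      element = toupper(element),
      resname = trimws(substr(ln, 18, 20)),
      resnum = as.integer(num_field(substr(ln, 23, 26), "residue number", idx)),
      chain = substr(ln, 22, 22),
      x = num_field(substr(ln, 31, 38), "x", idx),
      y = num_field(substr(ln, 39, 46), "y", idx),
      z = num_field(substr(ln, 47, 54), "z", idx),
      stringsAsFactors = FALSE
    )
  }

  if (!has_models) {
    atoms <- parse_block(atom_lines)
    sys <- molecular_system(atoms)
    if (model_policy == "first") return(sys)
    return(trajectory(sys, list(coords(sys)), times = times))
  }

  blocks <- split(atom_lines, model_id[atom_lines])
  first_atoms <- parse_block(blocks[[1L]])
  sys <- molecular_system(first_atoms)
  if (model_policy == "first") return(sys)

  counts <- lengths(blocks)
  if (length(unique(counts)) != 1L)
    .stopf("inconsistent atom count across MODELs: %s",
           paste(unique(counts), collapse = " vs "))
  frames <- lapply(blocks, function(idx) {
    a <- parse_block(idx)
    if (!identical(paste(a$chain, a$resnum, a$name),
                   paste(first_atoms$chain, first_atoms$resnum, first_atoms$name)))
      .stopf("atom identity differs between MODELs")
    as.matrix(a[, c("x", "y", "z")])
  })
  trajectory(sys, unname(frames), times = times)
}

#' Write a PDB file
#'
#' Writes fixed-column ATOM records (three decimals on coordinates, the
#' PDB precision limit).  A `trajectory` is written as MODEL/ENDMDL
#' blocks, one per frame, so [read_pdb()] round-trips it.
#'
#' @param x a `molecular_system` or `trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_atom <- function(a, xyz) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            a$serial, a$name, a$resname, a$chain,
            a$resnum, xyz[, 1], xyz[, 2], xyz[, 3], a$element)
  }
  if (inherits(x, "trajectory")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_along(x$frames)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(fmt_atom(x$system$atoms, x$frames[[f]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else if (inherits(x, "molecular_system")) {
    writeLines(c(fmt_atom(x$atoms, coords(x)), "END"), path)
  } else {
    .stopf("write_pdb expects a molecular_system or trajectory")
  }
  invisible(path)
}
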