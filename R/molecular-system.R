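#' Molecular system container
#'
#' A `molecular_system` holds an ordered atom table (coordinates in Angstrom,
#' partial charges in e, Lennard-Jones parameters in kcal/mol and Angstrom,
#' intrinsic Born radii in Angstrom, masses in amu) together with a disjoint,
#' exhaustive receptor/ligand partition.  It is the input to the interaction
#' energy, solvation and descriptor routines.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resnum`, `chain`, `x`, `y`, `z` and optionally `charge`,
#'   `epsilon`, `rmin_half`, `radius`, `mass`, `group`.  Missing parameter
#'   columns default to inert atoms (charge 0, epsilon 0) with
#'   element-default radii and masses, so geometry-only analyses work on
#'   bare PDBs.
#' @param receptor,ligand integer indices into `atoms` forming the partition.
#'   If omitted and `atoms$group` exists ("R"/"L"), the partition is taken
#'   from there; otherwise all atoms are assigned to the receptor.
#' @return An object of class `molecular_system`: a list with elements
#'   `atoms` (the completed atom table), `receptor`, `ligand` (index
#'   vectors) and `residues` (per-residue index, one row per residue in
#'   order of first appearance).
#' @examples
#' sys <- make_toy_complex(toy_complex_spec(seed = 1))
#' sys
#' n_atoms(sys)
#' @export
molecular_system <- function(atoms, receptor = NULL, ligand = NULL) {
  required <- c("serial", "name", "element", "resname", "resnum", "chain",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    .stopf("atom table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  n <- nrow(atoms)
  if (n < 1L) .stopf("empty atom table")

  atoms$charge    <- atoms$charge    %||% rep(0, n)
  atoms$epsilon   <- atoms$epsilon   %||% rep(0, n)
  atoms$rmin_half <- atoms$rmin_half %||% .default_radius(atoms$element)
  atoms$radius    <- atoms$radius    %||% .default_radius(atoms$element)
  atoms$mass      <- atoms$mass      %||% .default_mass(atoms$element)

  if (any(atoms$epsilon < 0)) .stopf("lj epsilon must be >= 0")
  if (any(atoms$mass <= 0)) .stopf("atom masses must be > 0")
  if (any(atoms$radius <= 0)) .stopf("Born radius seeds must be > 0")

  key <- paste(atoms$chain, atoms$resnum, atoms$name, sep = "/")
  if (anyDuplicated(key))
    .stopf("duplicate atom identity (chain/resnum/name): %s",
           key[duplicated(key)][1L])

  if (is.null(receptor) && is.null(ligand)) {
    if (!is.null(atoms$group)) {
      grp <- toupper(as.character(atoms$group))
      if (!all(grp %in% c("R", "L")))
        .stopf("group labels must be 'R' or 'L'")
      receptor <- which(grp == "R")
      ligand <- which(grp == "L")
    } else {
      receptor <- seq_len(n)
      ligand <- integer(0)
    }
  }
  receptor <- as.integer(receptor %||% integer(0))
  ligand <- as.integer(ligand %||% integer(0))
  if (length(intersect(receptor, ligand)))
    .stopf("receptor and ligand groups overlap")
  if (!setequal(union(receptor, ligand), seq_len(n)))
    .stopf("receptor and ligand groups must partition all %d atoms", n)

  rid <- paste(atoms$chain, atoms$resnum, sep = "/")
  first <- !duplicated(rid)
  residues <- data.frame(
    chain = atoms$chain[first],
    resnum = atoms$resnum[first],
    resname = atoms$resname[first],
    stringsAsFactors = FALSE
  )
  residues$atom_index <- lapply(
    paste(residues$chain, residues$resnum, sep = "/"),
    function(k) which(rid == k)
  )

  structure(
    list(atoms = atoms, receptor = receptor, ligand = ligand,
         residues = residues),
    class = "molecular_system"
  )
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf(
    "molecular_system: %d atoms, %d residues (receptor %d atoms, ligand %d atoms)\n",
    nrow(x$atoms), nrow(x$residues), length(x$receptor), length(x$ligand)))
  invisible(x)
}

#' Number of atoms in a system or trajectory
#' @param x a `molecular_system` or `trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) nrow(x$system$atoms) else nrow(x$atoms)
}

#' Coordinates of a system as an n x 3 matrix (Angstrom)
#' @param system a `molecular_system`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

#' Trajectory container
#'
#' An ordered set of coordinate frames over a fixed atom set.  Frames are
#' stored as a list of n_atoms x 3 matrices in Angstrom with strictly
#' increasing time stamps in ns.
#'
#' @param system the `molecular_system` the frames refer to.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param times numeric vector of frame times (ns), strictly increasing;
#'   defaults to 0, 1, 2, ...
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(system, frames, times = NULL) {
  if (!inherits(system, "molecular_system"))
    .stopf("system must be a molecular_system")
  if (!length(frames)) .stopf("trajectory needs at least one frame")
  n <- nrow(system$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3,
               logical(1))
  if (!all(ok))
    .stopf("frame %d does not match the system atom count (%d)",
           which(!ok)[1L], n)
  times <- times %||% (seq_along(frames) - 1)
  if (length(times) != length(frames))
    .stopf("times length (%d) != number of frames (%d)",
           length(times), length(frames))
  if (length(times) > 1 && any(diff(times) <= 0))
    .stopf("frame times must be strictly increasing")
  structure(list(system = system, frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %.4g..%.4g ns\n",
              length(x$frames), nrow(x$system$atoms),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Atom selections
#'
#' `select_backbone()` returns the indices of backbone N, CA, C atoms
#' (the GROMACS "backbone" group; carbonyl O excluded); `select_calpha()`
#' the indices of CA atoms, one per residue.  Both are restricted to the
#' receptor by default since descriptor analyses target the protein.
#'
#' @param system a `molecular_system`.
#' @param receptor_only restrict to receptor atoms (default TRUE).
#' @return integer vector of atom indices.
#' @export
select_backbone <- function(system, receptor_only = TRUE) {
  idx <- which(trimws(system$atoms$name) %in% c("N", "CA", "C"))
  if (receptor_only) idx <- intersect(idx, system$receptor)
  idx
}

#' @rdname select_backbone
#' @export
select_calpha <- function(system, receptor_only = TRUE) {
  idx <- which(trimws(system$atoms$name) == "CA")
  if (receptor_only) idx <- intersect(idx, system$receptor)
  idx
}
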