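#' Merge a topology table into a molecular system
#'
#' Topology CSVs carry the per-atom parameters the PDB format cannot:
#' partial charge (e), Lennard-Jones epsilon (kcal/mol) and rmin/2
#' (Angstrom), intrinsic Born radius (Angstrom), mass (amu) and the
#' receptor/ligand group label ("R"/"L").  Every atom of the system must be
#' matched exactly once on (chain, resnum, atomname).
#'
#' @param path CSV with header
#'   `chain,resnum,atomname,charge,epsilon,rmin_half,radius,mass,group`.
#' @param system the `molecular_system` to annotate.
#' @return A new `molecular_system` with parameters and the
#'   receptor/ligand partition set.
#' @export
read_topology <- function(path, system) {
  if (!file.exists(path)) .stopf("topology file not found: %s", path)
  top <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(chain = "character"))
  required <- c("chain", "resnum", "atomname", "charge", "epsilon",
                "rmin_half", "radius", "mass", "group")
  missing_cols <- setdiff(required, names(top))
  if (length(missing_cols))
    .stopf("topology lacks column(s): %s", paste(missing_cols, collapse = ", "))

  tkey <- paste(top$chain, top$resnum, trimws(top$atomname), sep = "/")
  if (anyDuplicated(tkey))
    .stopf("duplicate topology row for atom %s", tkey[duplicated(tkey)][1L])

  atoms <- system$atoms
  akey <- paste(atoms$chain, atoms$resnum, trimws(atoms$name), sep = "/")
  pos <- match(akey, tkey)
  if (anyNA(pos))
    .stopf("topology does not cover atom(s): %s",
           paste(utils::head(akey[is.na(pos)], 5L), collapse = ", "))
  extra <- setdiff(tkey, akey)
  if (length(extra))
    .stopf("topology row(s) reference nonexistent atom(s): %s",
           paste(utils::head(extra, 5L), collapse = ", "))

  atoms$charge <- top$charge[pos]
  atoms$epsilon <- top$epsilon[pos]
  atoms$rmin_half <- top$rmin_half[pos]
  atoms$radius <- top$radius[pos]
  atoms$mass <- top$mass[pos]
  atoms$group <- toupper(top$group[pos])
  molecular_system(atoms)
}

#' Write the topology table of a system
#' @param system a `molecular_system` with its partition set.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(system, path) {
  a <- system$atoms
  grp <- rep("R", nrow(a))
  grp[system$ligand] <- "L"
  utils::write.csv(
    data.frame(chain = a$chain, resnum = a$resnum, atomname = a$name,
               charge = a$charge, epsilon = a$epsilon,
               rmin_half = a$rmin_half, radius = a$radius, mass = a$mass,
               group = grp, stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fluorescence titration series
#'
#' Holds a saturation or competition fluorescence titration: probe or
#' competitor concentrations (uM) against fluorescence intensity
#' (counts/second), possibly replicated.
#'
#' @param concentrations non-negative, non-decreasing concentrations (uM),
#'   one per observation (replicates repeat the concentration).
#' @param intensities fluorescence intensities (counts/s), same length.
#' @param replicate integer replicate label per observation.
#' @param ph_label condition label, e.g. `"pH 7.4"`.
#' @param radioligand_conc fixed probe concentration (uM) for competition
#'   series; `NA` for saturation series.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(concentrations, intensities,
                             replicate = rep(1L, length(concentrations)),
                             ph_label = "", radioligand_conc = NA_real_) {
  if (length(concentrations) != length(intensities))
    .stopf("concentrations and intensities differ in length")
  if (any(concentrations < 0)) .stopf("concentrations must be non-negative")
  o <- order(concentrations, replicate)
  concentrations <- concentrations[o]
  intensities <- intensities[o]
  replicate <- replicate[o]
  structure(
    list(data = data.frame(conc_uM = concentrations, intensity = intensities,
                           replicate = as.integer(replicate)),
         ph_label = ph_label,
         radioligand_conc = radioligand_conc,
         n_replicates = length(unique(replicate))),
    class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series%s: %d concentrations x %d replicate(s)%s\n",
              if (nzchar(x$ph_label)) paste0(" [", x$ph_label, "]") else "",
              length(unique(x$data$conc_uM)), x$n_replicates,
              if (!is.na(x$radioligand_conc))
                sprintf(", probe %.3g uM", x$radioligand_conc) else ""))
  invisible(x)
}

#' Read/write titration CSVs
#'
#' Column layout: `conc_uM,intensity,replicate,series_id`.  On read, one
#' `titration_series` per distinct `series_id` is returned (a single
#' object when only one id is present).
#'
#' @param path CSV path.
#' @param radioligand_conc probe concentration (uM) to attach to every
#'   series read (competition data); `NA` for saturation data.
#' @return `read_titration_csv()`: a `titration_series` or named list of
#'   them; `write_titration_csv()`: `path`, invisibly.
#' @export
read_titration_csv <- function(path, radioligand_conc = NA_real_) {
  if (!file.exists(path)) .stopf("titration file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("conc_uM", "intensity", "replicate", "series_id")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    .stopf("titration CSV lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  out <- lapply(split(d, d$series_id), function(s)
    titration_series(s$conc_uM, s$intensity, s$replicate,
                     ph_label = s$series_id[1L],
                     radioligand_conc = radioligand_conc))
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname read_titration_csv
#' @param series a `titration_series`.
#' @param series_id id written to the `series_id` column.
#' @export
write_titration_csv <- function(series, path, series_id = "series1") {
  d <- series$data
  d$series_id <- series_id
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Model (reference) pKa values of titratable side chains, as used by the
## pKa-prediction software whose tables this package consumes.
.model_pka <- c(ASP = 3.80, GLU = 4.50, HIS = 6.50, CYS = 9.00,
                TYR = 10.00, LYS = 10.50, ARG = 12.50)

#' Per-residue pKa table
#'
#' Stores predicted pKa values per titratable residue and condition.
#' Predictions reported as "> 12" (a ceiling the prediction software
#' prints for effectively non-titrating sites) are stored as 12.0 with an
#' `at_ceiling` flag; downstream averages count them as exactly 12.
#'
#' @param rows data.frame with columns `residue_name`, `residue_number`,
#'   `condition`, `pka` (numeric) and `at_ceiling` (logical).
#' @return An object of class `pka_table` with the rows plus a
#'   `model_pka` map attached.
#' @export
pka_table <- function(rows) {
  required <- c("residue_name", "residue_number", "condition", "pka",
                "at_ceiling")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols))
    .stopf("pKa table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  rows$residue_name <- toupper(rows$residue_name)
  unknown <- setdiff(unique(rows$residue_name), names(.model_pka))
  if (length(unknown))
    .stopf("unknown titratable residue name(s): %s",
           paste(unknown, collapse = ", "))
  if (any(rows$at_ceiling & rows$pka != 12.0))
    .stopf("ceiling-flagged rows must carry pKa 12.0")
  structure(list(rows = rows, model_pka = .model_pka),
            class = "pka_table")
}

#' @export
print.pka_table <- function(x, ...) {
  cat(sprintf("pka_table: %d residues x %d condition(s)\n",
              length(unique(paste(x$rows$residue_name, x$rows$residue_number))),
              length(unique(x$rows$condition))))
  invisible(x)
}

#' Read a pKa prediction CSV
#'
#' Expected columns: `residue_name,residue_number,condition,pka`.  The
#' `pka` column may contain the string `">12"` (or `"> 12"`), which is
#' stored as 12.0 with the `at_ceiling` flag set.
#'
#' @param path CSV path.
#' @return A [pka_table()].
#' @export
read_pka_csv <- function(path) {
  if (!file.exists(path)) .stopf("pKa file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(pka = "character"))
  required <- c("residue_name", "residue_number", "condition", "pka")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    .stopf("pKa CSV lacks column(s): %s", paste(missing_cols, collapse = ", "))
  raw <- gsub(" ", "", d$pka)
  ceiling_flag <- raw == ">12"
  val <- suppressWarnings(as.numeric(raw))
  val[ceiling_flag] <- 12.0
  if (anyNA(val))
    .stopf("non-numeric pKa cell (other than '>12'): '%s'",
           d$pka[is.na(val)][1L])
  pka_table(data.frame(
    residue_name = d$residue_name,
    residue_number = as.integer(d$residue_number),
    condition = d$condition,
    pka = val,
    at_ceiling = ceiling_flag,
    stringsAsFactors = FALSE))
}
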