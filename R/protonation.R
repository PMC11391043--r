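## Group membership used for the acidic/basic/neutral summary rows.
.pka_groups <- list(
  acidic = c("ASP", "GLU"),
  basic = c("HIS", "LYS", "ARG"),
  neutral = c("CYS", "TYR")
)

#' Henderson-Hasselbalch protonated fraction
#'
#' `f = 1 / (1 + 10^(pH - pKa))`: strictly decreasing in pH, strictly
#' increasing in pKa, and 1/2 at pH = pKa.
#'
#' @param pka site pKa.
#' @param ph solution pH.
#' @return protonated fraction in \[0, 1\]; vectorised.
#' @export
fraction_protonated <- function(pka, ph) {
  1 / (1 + 10^(ph - pka))
}

#' Group-average pKa for one condition
#'
#' Mean predicted pKa over the residues of a group (acidic = Asp+Glu,
#' basic = His+Lys+Arg, neutral = Cys+Tyr) for one condition column,
#' with ceiling-flagged ("> 12") entries counted as exactly the ceiling
#' value.  Report cells are rounded half-up to 2 decimals; the full
#' precision value is returned.
#'
#' @param table a [pka_table()].
#' @param condition condition label present in the table.
#' @param group `"acidic"`, `"basic"` or `"neutral"`.
#' @param ceiling value substituted for ceiling-flagged entries
#'   (default 12).
#' @return mean pKa (full precision; apply [round_half_up()] for report
#'   formatting).
#' @export
group_average_pka <- function(table, condition,
                              group = c("acidic", "basic", "neutral"),
                              ceiling = 12.0) {
  group <- match.arg(group)
  if (!inherits(table, "pka_table")) .stopf("table must be a pka_table")
  rows <- table$rows[table$rows$condition == condition, ]
  if (!nrow(rows)) .stopf("condition '%s' not present in table", condition)
  sel <- rows$residue_name %in% .pka_groups[[group]]
  if (!any(sel)) .stopf("no %s residues for condition '%s'", group, condition)
  v <- rows$pka[sel]
  v[rows$at_ceiling[sel]] <- ceiling
  mean(v)
}

#' Acidic/basic/neutral protonation summary for one condition
#'
#' The three group-average pKas (report-rounded to 2 decimals, half-up)
#' plus, when `ph` is given, the Henderson-Hasselbalch protonated
#' fraction of every residue at that pH.
#'
#' @param table a [pka_table()].
#' @param condition condition label.
#' @param ph optional pH at which to evaluate per-residue fractions.
#' @param ceiling ceiling substitution value (default 12).
#' @return An object of class `protonation_summary` with `group_means`
#'   (rounded), `group_means_full`, `residue_fractions` (or NULL),
#'   `condition`, `ph`.
#' @export
protonation_summary <- function(table, condition, ph = NULL, ceiling = 12.0) {
  full <- vapply(names(.pka_groups), function(g)
    group_average_pka(table, condition, g, ceiling), numeric(1))
  fractions <- NULL
  if (!is.null(ph)) {
    rows <- table$rows[table$rows$condition == condition, ]
    v <- rows$pka
    v[rows$at_ceiling] <- ceiling
    fractions <- data.frame(
      residue_name = rows$residue_name,
      residue_number = rows$residue_number,
      pka = v,
      fraction = fraction_protonated(v, ph))
  }
  structure(list(group_means = round_half_up(full, 2),
                 group_means_full = full,
                 residue_fractions = fractions,
                 condition = condition, ph = ph),
            class = "protonation_summary")
}

#' @export
print.protonation_summary <- function(x, ...) {
  cat(sprintf("Protonation summary [%s]%s\n", x$condition,
              if (!is.null(x$ph)) sprintf(" at pH %.2f", x$ph) else ""))
  cat(sprintf("  mean pKa: acidic %.2f, basic %.2f, neutral %.2f\n",
              x$group_means[["acidic"]], x$group_means[["basic"]],
              x$group_means[["neutral"]]))
  invisible(x)
}

#' Expected per-residue charges at a given pH
#'
#' Titratable acids (Asp, Glu, Cys, Tyr) contribute
#' `-(1 - fraction_protonated)`, titratable bases (His, Lys, Arg)
#' contribute `+fraction_protonated`.  Residues of the system missing
#' from the table fall back (with a warning) on the model pKa of their
#' residue type.  Total expected charge is monotonically non-increasing
#' in pH.
#'
#' @param system a `molecular_system` (its receptor residues are
#'   scanned for titratable residue names), or `NULL` to use every
#'   residue in the table.
#' @param table a [pka_table()].
#' @param ph solution pH.
#' @param condition condition column of the table to use; default: its
#'   first condition.
#' @return list with `residues` (data.frame: residue_name,
#'   residue_number, pka, fraction, charge) and `total_charge`.
#' @export
assign_charges_at_ph <- function(system = NULL, table, ph,
                                 condition = NULL) {
  if (!inherits(table, "pka_table")) .stopf("table must be a pka_table")
  condition <- condition %||% table$rows$condition[1L]
  rows <- table$rows[table$rows$condition == condition, ]
  if (!nrow(rows)) .stopf("condition '%s' not present in table", condition)
  v <- rows$pka
  v[rows$at_ceiling] <- 12.0

  if (!is.null(system)) {
    res <- system$residues
    titr <- res[toupper(res$resname) %in% names(.model_pka), ]
    pos <- match(paste(toupper(titr$resname), titr$resnum),
                 paste(rows$residue_name, rows$residue_number))
    pka <- v[pos]
    missing <- is.na(pos)
    if (any(missing)) {
      .warnf("residue(s) missing from pKa table, using model pKa: %s",
             paste(paste0(titr$resname[missing], titr$resnum[missing]),
                   collapse = ", "))
      pka[missing] <- .model_pka[toupper(titr$resname[missing])]
    }
    names_ <- toupper(titr$resname); nums <- titr$resnum
  } else {
    pka <- v; names_ <- rows$residue_name; nums <- rows$residue_number
  }

  f <- fraction_protonated(pka, ph)
  is_base <- names_ %in% c("HIS", "LYS", "ARG")
  charge <- ifelse(is_base, f, -(1 - f))
  list(residues = data.frame(residue_name = names_, residue_number = nums,
                             pka = pka, fraction = f, charge = charge),
       total_charge = sum(charge), ph = ph, condition = condition)
}

#' Flag residues with large pKa shifts
#'
#' Residues whose predicted pKa deviates from the model (reference) pKa
#' of their residue type by at least `threshold` units, sorted by shift
#' magnitude.  Such shifts mark sites whose protonation is perturbed by
#' the protein environment.
#'
#' @param table a [pka_table()].
#' @param threshold minimum |predicted - model| shift (default 1.5).
#' @param condition restrict to one condition (default: all).
#' @return data.frame with `residue_name`, `residue_number`, `condition`,
#'   `pka`, `model_pka`, `shift`, sorted by decreasing |shift|.
#' @export
flag_shifted_residues <- function(table, threshold = 1.5, condition = NULL) {
  if (!inherits(table, "pka_table")) .stopf("table must be a pka_table")
  rows <- table$rows
  if (!is.null(condition)) rows <- rows[rows$condition %in% condition, ]
  v <- rows$pka
  v[rows$at_ceiling] <- 12.0
  model <- table$model_pka[rows$residue_name]
  shift <- v - model
  keep <- abs(shift) >= threshold
  out <- data.frame(residue_name = rows$residue_name[keep],
                    residue_number = rows$residue_number[keep],
                    condition = rows$condition[keep],
                    pka = v[keep], model_pka = unname(model[keep]),
                    shift = unname(shift[keep]))
  out <- out[order(-abs(out$shift)), ]
  rownames(out) <- NULL
  out
}
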