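#' Pipeline configuration
#'
#' Describes a two-condition comparison run.  Each condition (e.g. one pH)
#' carries its own binding constants and fluctuation scale for the
#' synthetic stages, or file paths for pre-existing inputs.  Stage
#' settings other than the pH-dependent inputs are shared, so the two
#' conditions are computed identically.
#'
#' @param output_dir directory for artifacts (created on run).
#' @param conditions list of exactly two condition lists, each with
#'   elements `label` (distinct), `ph`, `kd_true`, `ki_true` (named
#'   vector, one entry per competitor ligand), `sigma_core`,
#'   `sigma_loose`, `loose_selection`, and optionally `traj_pdb` /
#'   `saturation_csv` / `competition_csv` paths that override the
#'   synthetic generators, plus `pka_condition` naming the condition
#'   column of the pKa table.
#' @param complex_pdb,topology_csv optional paths to a complex structure
#'   and topology; when NULL a toy complex is generated.
#' @param pka_csv path to a pKa prediction CSV; default: the bundled
#'   table.
#' @param n_frames trajectory length for the synthetic stages.
#' @param temperature K.
#' @param seed master seed.
#' @param solvation_stride,n_sphere_points energetics settings (see
#'   [mmpbsa_summary()]).
#' @return A list of class `pipeline_config`, validated.
#' @export
pipeline_config <- function(output_dir,
                            conditions = list(
                              list(label = "pH 7.4", ph = 7.4,
                                   kd_true = 2.33,
                                   ki_true = c(farnesene = 0.72,
                                               caryophyllene = 1.06,
                                               octenol = 2.00),
                                   sigma_core = 0.3, sigma_loose = 0.3,
                                   loose_selection = integer(0),
                                   pka_condition = "farnesene_pH7.4"),
                              list(label = "pH 5.5", ph = 5.5,
                                   kd_true = 4.83,
                                   ki_true = c(farnesene = 1.24,
                                               caryophyllene = 15.99,
                                               octenol = 5.61),
                                   sigma_core = 0.3, sigma_loose = 0.9,
                                   loose_selection = 1:4,
                                   pka_condition = "farnesene_pH5.5")),
                            complex_pdb = NULL, topology_csv = NULL,
                            pka_csv = NULL,
                            n_frames = 60L, temperature = 300,
                            seed = 1L, solvation_stride = 10L,
                            n_sphere_points = 240L) {
  if (length(conditions) != 2L) .stopf("exactly two conditions are required")
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (labels[1] == labels[2]) .stopf("condition labels must be distinct")
  pka_csv <- pka_csv %||% system.file("extdata", "solg21_pka_predictions.csv",
                                      package = "phbind")
  paths <- c(complex_pdb = complex_pdb, topology_csv = topology_csv,
             pka_csv = pka_csv,
             unlist(lapply(conditions, function(cc)
               cc[intersect(names(cc),
                            c("traj_pdb", "saturation_csv", "competition_csv"))])))
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      .stopf("config path '%s' does not exist: %s", nm, paths[[nm]])
  if (!is.null(complex_pdb) && is.null(topology_csv))
    .stopf("config path 'topology_csv' is required with 'complex_pdb'")
  structure(list(output_dir = output_dir, conditions = conditions,
                 complex_pdb = complex_pdb, topology_csv = topology_csv,
                 pka_csv = pka_csv, n_frames = as.integer(n_frames),
                 temperature = temperature, seed = as.integer(seed),
                 solvation_stride = as.integer(solvation_stride),
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "pipeline_config")
}

#' Run the end-to-end two-condition pipeline
#'
#' Executes, per condition: input generation (or loading), saturation and
#' competition fits, trajectory descriptors (RMSD, RMSF, Rg, SASA),
#' MM-PBSA-style free-energy summary with interaction entropy and
#' per-residue decomposition, protonation summary, and Cartesian PCA with
#' spread metrics.  Artifacts (CSV/JSON/PDB) are written under
#' `config$output_dir` together with a manifest of inputs, seeds and md5
#' hashes; a rerun with the same config reproduces identical numbers.
#'
#' @param config a [pipeline_config()].
#' @return A `condition_comparison` object (see [render_report()]).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    .stopf("config must be a pipeline_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[phbind] ", fmt), ...))

  log_stage("stage system: %s",
            if (is.null(config$complex_pdb)) "toy complex" else config$complex_pdb)
  sys <- if (is.null(config$complex_pdb)) {
    make_toy_complex(toy_complex_spec(seed = config$seed))
  } else {
    read_topology(config$topology_csv, read_pdb(config$complex_pdb, "first"))
  }
  write_pdb(sys, out("complex.pdb"))
  write_topology(sys, out("topology.csv"))
  pka <- read_pka_csv(config$pka_csv)

  per_condition <- lapply(seq_along(config$conditions), function(ci) {
    cc <- config$conditions[[ci]]
    tag <- gsub("[^A-Za-z0-9.]+", "_", cc$label)
    log_stage("condition %s", cc$label)

    traj <- if (!is.null(cc$traj_pdb)) {
      read_pdb(cc$traj_pdb, "all")
    } else {
      simulate_trajectory(sys, fluctuation_spec(
        n_frames = config$n_frames, sigma_core = cc$sigma_core,
        sigma_loose = cc$sigma_loose,
        loose_selection = cc$loose_selection,
        seed = config$seed + 10L * ci))
    }
    traj$system <- sys
    write_pdb(traj, out(sprintf("traj_%s.pdb", tag)))

    sat_series <- if (!is.null(cc$saturation_csv)) {
      read_titration_csv(cc$saturation_csv)
    } else {
      simulate_titration(kd = cc$kd_true, bmax = 1e6, ph_label = cc$label,
                         seed = config$seed + 100L * ci)
    }
    sat <- fit_saturation(sat_series)
    comps <- lapply(seq_along(cc$ki_true), function(li)
      fit_competition(
        simulate_competition(ki = cc$ki_true[[li]], kd_probe = sat$kd,
                             radioligand_conc = 5, ph_label = cc$label,
                             seed = config$seed + 100L * ci + li),
        kd_probe = sat$kd))
    ranking <- rank_affinities(comps, names(cc$ki_true))

    log_stage("  descriptors")
    rmsd <- rmsd_series(traj)
    rmsf <- rmsf_profile(traj)
    rg <- radius_of_gyration(traj)
    sasa_s <- sasa_series(traj,
                          n_sphere_points = config$n_sphere_points)

    log_stage("  energetics")
    fes <- mmpbsa_summary(traj, temperature = config$temperature,
                          solvation_stride = config$solvation_stride,
                          n_sphere_points = config$n_sphere_points)
    decomp <- residue_decomposition(traj)

    prot <- protonation_summary(pka, cc$pka_condition, ph = cc$ph)
    pca_res <- cartesian_pca(traj)
    spread <- spread_metrics(pca_res)

    utils::write.csv(data.frame(time_ns = rmsd$times, rmsd_A = rmsd$values,
                                rg_nm = rg$values, sasa_nm2 = sasa_s$values),
                     out(sprintf("descriptors_%s.csv", tag)), row.names = FALSE)
    utils::write.csv(as.data.frame(rmsf),
                     out(sprintf("rmsf_%s.csv", tag)), row.names = FALSE)
    utils::write.csv(as.data.frame(decomp),
                     out(sprintf("residue_decomposition_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(data.frame(time_ns = pca_res$times,
                                PC1_nm = pca_res$projections[, 1],
                                PC2_nm = pca_res$projections[, 2]),
                     out(sprintf("pca_%s.csv", tag)), row.names = FALSE)
    jsonlite::write_json(
      list(label = cc$label, ph = cc$ph,
           saturation = list(kd_uM = sat$kd, se_kd = sat$se_kd,
                             bmax = sat$bmax, r_squared = sat$r_squared,
                             scatchard_kd_uM = sat$scatchard_kd),
           ki_uM = stats::setNames(as.list(ranking$ki_uM), ranking$label),
           descriptor_means = list(rmsd_A = rmsd$mean, rg_nm = rg$mean,
                                   sasa_nm2 = sasa_s$mean,
                                   rmsf_A = mean(rmsf$rmsf)),
           free_energy = as.data.frame(fes),
           protonation_group_means = as.list(prot$group_means),
           pca_spread = list(pc1_range = spread$ranges[1, ],
                             pc2_range = spread$ranges[2, ],
                             compactness_nm = spread$compactness)),
      out(sprintf("summary_%s.json", tag)), auto_unbox = TRUE, digits = NA)

    list(label = cc$label, ph = cc$ph, saturation = sat,
         competition = comps, ranking = ranking,
         rmsd = rmsd, rmsf = rmsf, rg = rg, sasa = sasa_s,
         free_energy = fes, decomposition = decomp,
         protonation = prot, pca = pca_res, spread = spread)
  })

  files <- setdiff(list.files(config$output_dir, full.names = TRUE),
                   out("manifest.json"))
  manifest <- list(
    package = "phbind",
    version = as.character(utils::packageVersion("phbind")),
    seed = config$seed,
    temperature = config$temperature,
    n_frames = config$n_frames,
    conditions = vapply(config$conditions, `[[`, character(1), "label"),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  structure(list(conditions = per_condition, config = config),
            class = "condition_comparison")
}

#' Render a two-condition comparison report
#'
#' Produces a plain-text report with the affinity (Ki) table, the
#' free-energy term table (same columns as the standard MM-PBSA + -TdS
#' layout), the protonation group means and the descriptor/PCA spread
#' summary, each with a delta column (condition 2 minus condition 1).
#' Numbers are shown at 2 decimals; full precision lives in the
#' machine-readable pipeline artifacts.
#'
#' @param cmp a `condition_comparison` from [run_pipeline()].
#' @return character vector of report lines, invisibly; the report is
#'   also printed.
#' @export
render_report <- function(cmp) {
  if (!inherits(cmp, "condition_comparison"))
    .stopf("cmp must be a condition_comparison")
  c1 <- cmp$conditions[[1L]]; c2 <- cmp$conditions[[2L]]
  f2 <- function(x) sprintf("%8.2f", x)
  lines <- c(
    sprintf("phbind condition comparison: %s vs %s", c1$label, c2$label), "")

  lines <- c(lines, "Probe dissociation constant (uM)",
             sprintf("  %-14s %8.2f", c1$label, c1$saturation$kd),
             sprintf("  %-14s %8.2f", c2$label, c2$saturation$kd),
             sprintf("  %-14s %8.2f", "delta", c2$saturation$kd - c1$saturation$kd),
             "", "Competitor Ki (uM)")
  r1 <- c1$ranking[order(c1$ranking$label), ]
  r2 <- c2$ranking[order(c2$ranking$label), ]
  lines <- c(lines,
             sprintf("  %-16s %10s %10s %10s", "ligand", c1$label, c2$label, "delta"),
             sprintf("  %-16s %10.2f %10.2f %10.2f",
                     r1$label, r1$ki_uM, r2$ki_uM, r2$ki_uM - r1$ki_uM))

  terms <- c("dG_ele", "dG_vdw", "dG_gas", "dG_np", "dG_pb", "dG_sol",
             "dG_mmpbsa", "minus_TdS", "dG_bind")
  lines <- c(lines, "",
             "Free-energy terms (kcal/mol; polar term: pb_surrogate(GB))",
             sprintf("  %-10s %10s %10s %10s", "term", c1$label, c2$label, "delta"))
  for (t in terms)
    lines <- c(lines, sprintf("  %-10s %10.2f %10.2f %10.2f",
                              t, c1$free_energy[[t]], c2$free_energy[[t]],
                              c2$free_energy[[t]] - c1$free_energy[[t]]))

  lines <- c(lines, "", "Group-average pKa",
             sprintf("  %-8s %10s %10s %10s", "group", c1$label, c2$label, "delta"))
  for (g in c("acidic", "basic", "neutral"))
    lines <- c(lines, sprintf("  %-8s %10.2f %10.2f %10.2f", g,
                              c1$protonation$group_means[[g]],
                              c2$protonation$group_means[[g]],
                              c2$protonation$group_means[[g]] -
                                c1$protonation$group_means[[g]]))

  lines <- c(lines, "", "Descriptor means and PCA spread",
             sprintf("  %-16s %10s %10s %10s", "metric", c1$label, c2$label, "delta"))
  met <- function(lbl, v1, v2)
    sprintf("  %-16s %10.2f %10.2f %10.2f", lbl, v1, v2, v2 - v1)
  lines <- c(lines,
             met("RMSD (A)", c1$rmsd$mean, c2$rmsd$mean),
             met("RMSF (A)", mean(c1$rmsf$rmsf), mean(c2$rmsf$rmsf)),
             met("Rg (nm)", c1$rg$mean, c2$rg$mean),
             met("SASA (nm^2)", c1$sasa$mean, c2$sasa$mean),
             met("PCA compactness", c1$spread$compactness, c2$spread$compactness))
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("condition_comparison: %s vs %s (call render_report() for tables)\n",
              x$conditions[[1L]]$label, x$conditions[[2L]]$label))
  invisible(x)
}
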