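# Reading and writing the package's CSV dialects, the cohort manifest, and
# the mapping-driven adapter for externally deposited tables.
#
# Kinematic CSV: one row per step — participant_id, step_index, x_pelvis,
# vx_pelvis, vy_pelvis, x_foot, y_foot (SI units, header required).
# Metabolic CSV: one row per breath — participant_id, condition, t_s,
# vo2_mls_kg, vco2_mls_kg. The energy rate is always recomputed from the gas
# fluxes on read, never stored.

kin_csv_cols <- c("participant_id", "step_index", "x_pelvis", "vx_pelvis",
                  "vy_pelvis", "x_foot", "y_foot")
met_csv_cols <- c("participant_id", "condition", "t_s", "vo2_mls_kg",
                  "vco2_mls_kg")

split_trials <- function(df) {
  out <- split(df, factor(df$participant_id, levels = unique(df$participant_id)))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Write / read a kinematic cohort CSV
#'
#' @param trials named list of kinematic trial data frames (or a cohort
#'   object; its `$trials` is used).
#' @param path file path.
#' @return `read_kinematic_csv()` returns a named list of per-participant
#'   trial data frames.
#' @export
write_kinematic_csv <- function(trials, path) {
  if (is.list(trials) && !is.null(trials$trials)) trials <- trials$trials
  df <- do.call(rbind, unname(trials))
  utils::write.csv(df[kin_csv_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematic_csv
#' @export
read_kinematic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(kin_csv_cols, names(df))
  if (length(miss))
    stopf("kinematic CSV %s is missing columns: %s", path,
          paste(miss, collapse = ", "))
  split_trials(df[kin_csv_cols])
}

#' Write / read a metabolic cohort CSV
#'
#' The stored table carries only times and gas fluxes; `read_metabolic_csv()`
#' fills the energy-rate column through [brockway_rate()].
#'
#' @param trials named list of metabolic trial data frames (or a cohort
#'   object).
#' @param path file path.
#' @return `read_metabolic_csv()` returns a named list of per-participant
#'   trial data frames with `edot_w_kg` computed.
#' @export
write_metabolic_csv <- function(trials, path) {
  if (is.list(trials) && !is.null(trials$trials)) trials <- trials$trials
  df <- do.call(rbind, unname(trials))
  utils::write.csv(df[met_csv_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolic_csv
#' @export
read_metabolic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(met_csv_cols, names(df))
  if (length(miss))
    stopf("metabolic CSV %s is missing columns: %s", path,
          paste(miss, collapse = ", "))
  df <- df[met_csv_cols]
  df$edot_w_kg <- brockway_rate(df$vo2_mls_kg, df$vco2_mls_kg)
  split_trials(df)
}

#' Write point estimates to a tidy CSV
#'
#' @param estimates data frame of point estimates.
#' @param path file path.
#' @export
write_estimates_csv <- function(estimates, path) {
  utils::write.csv(as.data.frame(estimates), path, row.names = FALSE)
  invisible(path)
}

#' Export a synthetic cohort with its manifest
#'
#' Writes the cohort's data CSV, its ground-truth table, and a JSON manifest
#' recording the generating spec (including the seed), so a directory is
#' sufficient to rerun or audit the simulation.
#'
#' @param cohort a `kinematic_cohort` or `metabolic_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  kinematic <- inherits(cohort, "kinematic_cohort")
  if (!kinematic && !inherits(cohort, "metabolic_cohort"))
    stopf("`cohort` must come from one of the simulate_* generators")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_file <- if (kinematic) "kinematic.csv" else "metabolic.csv"
  if (kinematic) write_kinematic_csv(cohort$trials, file.path(dir, data_file))
  else write_metabolic_csv(cohort$trials, file.path(dir, data_file))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  spec <- cohort$spec
  spec$pelvis_chol <- NULL
  manifest <- list(
    kind = if (kinematic) "kinematic" else "metabolic",
    data_file = data_file,
    truth_file = "truth.csv",
    n_participants = spec$n_participants,
    participant_ids = names(cohort$trials),
    spec = lapply(spec, function(v) if (is.matrix(v)) as.data.frame(v) else v)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load externally deposited step or breath tables via a column map
#'
#' Adapts a deposited CSV whose column names differ from this package's
#' dialect. `mapping` names the package's canonical columns and gives the
#' file's column for each; unmapped canonical columns must already be
#' present under their own names. Works for a single CSV file or a directory
#' written by [write_cohort()] (whose manifest names the data file).
#'
#' @param path a CSV file, or a directory containing `manifest.json`.
#' @param kind `"kinematic"` or `"metabolic"`.
#' @param mapping named character vector, e.g.
#'   `c(x_pelvis = "pelvis_x_m", x_foot = "foot_x_m")`.
#' @return A named list of per-participant trial data frames.
#' @export
load_cohort_tables <- function(path, kind = c("kinematic", "metabolic"),
                               mapping = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stopf("path does not exist: %s", path)
  if (dir.exists(path)) {
    mf <- file.path(path, "manifest.json")
    if (!file.exists(mf))
      stopf("directory %s has no manifest.json; found files: %s", path,
            paste(list.files(path), collapse = ", "))
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    path <- file.path(path, manifest$data_file)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    bad <- setdiff(unname(mapping), names(df))
    if (length(bad))
      stopf("mapped source columns not in file: %s; file has: %s",
            paste(bad, collapse = ", "), paste(names(df), collapse = ", "))
    for (canonical in names(mapping)) names(df)[names(df) == mapping[[canonical]]] <- canonical
  }
  need <- if (kind == "kinematic") kin_csv_cols else met_csv_cols
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("cannot adapt %s: missing columns %s; supply `mapping` keys for them (file has: %s)",
          path, paste(miss, collapse = ", "), paste(names(df), collapse = ", "))
  df <- df[need]
  if (kind == "metabolic")
    df$edot_w_kg <- brockway_rate(df$vo2_mls_kg, df$vco2_mls_kg)
  split_trials(df)
}

#' Serialize shrinkage and accuracy summaries to JSON
#'
#' @param result a [compute_shrinkage()] result.
#' @param comparison optional [compare_accuracy()] result.
#' @param path file path.
#' @export
write_shrinkage_json <- function(result, path, comparison = NULL) {
  out <- list(k = result$k,
              grand_mean = result$grand_mean,
              pooled_se2 = result$pooled_se2,
              raw_c = result$raw_c,
              applied_c = result$applied_c,
              positive_part_applied = result$positive_part_applied)
  if (!is.null(comparison)) {
    out$sse_mle <- comparison$sse_mle
    out$sse_jse <- comparison$sse_jse
    out$pct_reduction <- comparison$pct_reduction
    out$p_paired_errors <- comparison$p_paired_errors
    out$p_truth_vs_mle <- comparison$p_truth_vs_mle
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
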