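# File formats and end-to-end pipelines tying the stages together.
#
# CSV dialects (UTF-8, decimal point, '#' comment lines):
#   drying:    time_h,moisture_db[,replicate]
#   shrinkage: moisture_db,psi      (or moisture_db,a_mm,b_mm,c_mm)
#   storage:   harvest_moisture_pct,drying_temp,storage_temp_C,package,
#              time_months,replicate,moisture_pct,ec,oil_pct,acidity_ml,
#              protein_pct

#' Read a drying-curve CSV
#'
#' @param path CSV with columns `time_h` and `moisture_db` (and
#'   optionally `replicate`, averaged per time point); `#` lines are
#'   comments.
#' @param x0,xe,air_temp_C,label curve metadata (see [drying_curve()]);
#'   `x0` defaults to the first moisture value.
#' @return A [drying_curve()].
#' @export
read_drying_csv <- function(path, x0 = NULL, xe = NULL,
                            air_temp_C = NA_real_, label = path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) == 0) stop_contract("no data rows in ", path)
  miss <- setdiff(c("time_h", "moisture_db"), names(df))
  if (length(miss)) {
    stop_contract(path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  if ("replicate" %in% names(df)) {
    df <- stats::aggregate(moisture_db ~ time_h, data = df, FUN = mean)
  }
  df <- df[order(df$time_h), ]
  drying_curve(df$time_h, df$moisture_db,
               x0 = if (is.null(x0)) df$moisture_db[1] else x0,
               xe = xe, air_temp_C = air_temp_C, label = label)
}

#' Read a storage-records CSV
#'
#' @param path CSV in the storage dialect (see [gen_storage_table()] for
#'   the column set). A missing required column is a schema error naming
#'   the column.
#' @return Data frame of storage records.
#' @export
read_storage_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c(STORAGE_FACTORS, "replicate", STORAGE_VARIABLES)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_contract(path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Fit all (or selected) drying models to curves and rank them
#'
#' For each curve: computes the moisture ratio, fits every requested
#' thin-layer model by bounded multi-start least squares, ranks the fits,
#' and reports the best model with its fitted curve. Deterministic given
#' (curves, models, seed).
#'
#' @param curves a [drying_curve()] or list of them.
#' @param models model names to fit (default: all eleven).
#' @param n_starts,seed,alpha passed to [fit_model()].
#' @param p_threshold passed to [rank_models()].
#' @param out_dir optional directory; when given, per-curve ranking
#'   tables and best-model predictions are written as CSV.
#' @return List of per-curve results, each with `curve`, `mr`, `fits`
#'   (named list of `fit_result`), `ranking` (data frame), `best_model`,
#'   `best_curve` (data frame `time_h`, `mr_obs`, `mr_fit`).
#' @export
run_drying_pipeline <- function(curves, models = drying_models(),
                                n_starts = 8, seed = 1, alpha = 0.05,
                                p_threshold = 10, out_dir = NULL) {
  if (inherits(curves, "drying_curve")) curves <- list(curves)
  stopifnot(length(curves) > 0,
            all(vapply(curves, inherits, logical(1), "drying_curve")))
  models <- match.arg(models, drying_models(), several.ok = TRUE)
  out <- vector("list", length(curves))
  for (ci in seq_along(curves)) {
    curve <- curves[[ci]]
    mr <- moisture_ratio(curve)
    fits <- lapply(models, function(m) {
      fit_model(mr$time_h, mr$mr, drying_model(m), n_starts = n_starts,
                seed = seed + ci, alpha = alpha)
    })
    names(fits) <- models
    ranking <- rank_models(fits, p_threshold = p_threshold)
    best <- ranking$model[1]
    best_curve <- data.frame(time_h = mr$time_h, mr_obs = mr$mr,
                             mr_fit = fits[[best]]$fitted)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      stem <- file.path(out_dir, sprintf("curve%02d", ci))
      utils::write.csv(ranking, paste0(stem, "_ranking.csv"), row.names = FALSE)
      utils::write.csv(best_curve, paste0(stem, "_best_fit.csv"), row.names = FALSE)
    }
    out[[ci]] <- list(curve = curve, mr = mr, fits = fits, ranking = ranking,
                      best_model = best, best_curve = best_curve)
  }
  out
}

#' Multivariate storage-quality pipeline
#'
#' Treatment means over replicates, standardization, Ward/Euclidean
#' clustering into `k` groups, per-cluster Pearson correlations over the
#' raw variables, and compact-letter Tukey summaries of each quality
#' variable in the two directions customary for storage tables: across
#' storage times within each storage-condition cell (`letters_time`) and
#' across storage conditions within each time (`letters_condition`).
#'
#' @param records storage records (see [read_storage_csv()] or
#'   [gen_storage_table()]).
#' @param k number of clusters (default 4).
#' @param variables quality variables used for clustering (default all
#'   five).
#' @param alpha significance level for the Tukey letters.
#' @param out_dir optional directory for CSV outputs (labels, merge
#'   heights, per-cluster correlations, letter tables).
#' @return List with `means` (treatment matrix), `z`, `clusters`
#'   (`cluster_result`), `correlations`, `letters_time`,
#'   `letters_condition`.
#' @export
run_storage_pipeline <- function(records, k = 4,
                                 variables = STORAGE_VARIABLES,
                                 alpha = 0.05, out_dir = NULL) {
  m <- treatment_matrix(records, variables)
  z <- standardize(m)
  cl <- ward_cluster(z, k)
  cors <- cluster_correlations(m, cl$labels)

  cell_t <- interaction(records$harvest_moisture_pct, records$drying_temp,
                        records$storage_temp_C, records$package, drop = TRUE)
  letters_time <- .letters_by_group(records, variables, cell_t, "time_months", alpha)
  cell_c <- interaction(records$harvest_moisture_pct, records$drying_temp,
                        records$time_months, drop = TRUE)
  records$condition <- paste(records$storage_temp_C, records$package, sep = "/")
  letters_condition <- .letters_by_group(records, variables, cell_c, "condition", alpha)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(treatment = cl$treatment_ids, label = cl$labels),
                     file.path(out_dir, "cluster_labels.csv"), row.names = FALSE)
    utils::write.csv(data.frame(step = seq_along(cl$merge_heights),
                                height = cl$merge_heights),
                     file.path(out_dir, "merge_heights.csv"), row.names = FALSE)
    for (g in names(cors)) {
      utils::write.csv(cors[[g]],
                       file.path(out_dir, sprintf("correlations_group%s.csv", g)))
    }
    utils::write.csv(letters_time, file.path(out_dir, "letters_time.csv"),
                     row.names = FALSE)
    utils::write.csv(letters_condition,
                     file.path(out_dir, "letters_condition.csv"), row.names = FALSE)
  }
  list(means = m, z = z, clusters = cl, correlations = cors,
       letters_time = letters_time, letters_condition = letters_condition)
}

.letters_by_group <- function(records, variables, cell, factor, alpha) {
  out <- list()
  for (v in variables) {
    for (cg in levels(cell)) {
      sub <- records[cell == cg, , drop = FALSE]
      if (length(unique(sub[[factor]])) < 2) next
      lt <- tryCatch(tukey_letters(sub, v, factor, alpha),
                     error = function(e) NULL)
      if (is.null(lt)) next
      lt$variable <- v
      lt$cell <- cg
      out[[length(out) + 1]] <- lt
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}
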