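# Plain-text readers and writers. All tables are tab-separated with label
# headers; lines starting with '#' are metadata comments (config hash,
# seeds) and are skipped on read.

write_tsv_with_header <- function(tab, path, meta = NULL, row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

read_tsv_table <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a regional time series to a tab-separated table
#'
#' T rows x N regions with a header row of region labels.
#' @param ts `fn_timeseries`.
#' @param path file path.
#' @param meta optional metadata comment line.
#' @export
write_timeseries <- function(ts, path, meta = NULL) {
  stopifnot(inherits(ts, "fn_timeseries"))
  write_tsv_with_header(as.data.frame(ts$values), path, meta)
}

#' Read a regional time series table
#' @param path file path.
#' @param tr_seconds repetition time (seconds).
#' @param subject_id,group_label identifiers to attach.
#' @return `fn_timeseries`.
#' @export
read_timeseries <- function(path, tr_seconds, subject_id = basename(path),
                            group_label = NA_character_) {
  tab <- read_tsv_table(path)
  values <- as.matrix(tab)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stopf("time series %s contains non-finite or non-numeric values", path)
  }
  if (nrow(values) < 2) stopf("time series %s has fewer than 2 time points", path)
  structure(list(subject_id = subject_id, group_label = group_label,
                 values = values, tr_seconds = tr_seconds,
                 region_labels = colnames(values)),
            class = "fn_timeseries")
}

#' Write a symmetric labelled matrix (connectivity or weights)
#' @param m matrix with region dimnames.
#' @param path file path.
#' @param meta optional metadata comment line.
#' @export
write_matrix_tsv <- function(m, path, meta = NULL) {
  write_tsv_with_header(as.data.frame(m), path, meta, row_names = TRUE)
}

#' Read a symmetric labelled matrix
#' @param path file path.
#' @return matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- read_tsv_table(path, row.names = 1)
  as.matrix(tab)
}

#' Write a cohort to disk: one file per subject plus a manifest
#'
#' The manifest maps `subject_id` to `file` and `group`, with one
#' additional column per covariate (missing values written as `NA`).
#'
#' @param cohort `fn_cohort`.
#' @param dir output directory (created if needed).
#' @param meta optional metadata comment line for every file.
#' @return path of the manifest file.
#' @export
write_cohort <- function(cohort, dir, meta = NULL) {
  stopifnot(inherits(cohort, "fn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort$subjects, function(s) {
    f <- paste0("ts_", s$subject_id, ".tsv")
    write_timeseries(s, file.path(dir, f), meta)
    f
  }, character(1))
  manifest <- data.frame(subject_id = vapply(cohort$subjects, `[[`,
                                             character(1), "subject_id"),
                         file = files,
                         group = vapply(cohort$subjects, `[[`,
                                        character(1), "group_label"),
                         stringsAsFactors = FALSE)
  extra <- setdiff(names(cohort$covariates), c("subject_id", "group"))
  for (cv in extra) {
    manifest[[cv]] <- cohort$covariates[[cv]][
      match(manifest$subject_id, cohort$covariates$subject_id)]
  }
  path <- file.path(dir, "manifest.tsv")
  write_tsv_with_header(manifest, path, meta)
  path
}

#' Read a cohort from a subject manifest
#'
#' The manifest must have columns `subject_id`, `file`, `group`; file paths
#' are resolved relative to the manifest's directory. Every time series is
#' validated against the atlas (region count and labels). Additional
#' manifest columns become covariates (missing values allowed).
#'
#' @param path manifest file path.
#' @param tr_seconds repetition time of the series (seconds).
#' @param atlas optional `fn_atlas` to validate against.
#' @return `fn_cohort` (with `spec = NULL`).
#' @export
read_subject_manifest <- function(path, tr_seconds = 3, atlas = NULL) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  manifest <- read_tsv_table(path)
  need <- c("subject_id", "file", "group")
  if (!all(need %in% names(manifest))) {
    stopf("manifest %s must have columns subject_id, file, group", path)
  }
  bad_group <- !manifest$group %in% c("A", "B")
  if (any(bad_group)) {
    stopf("manifest %s line %d: unknown group label '%s'",
          path, which(bad_group)[1] + 1, manifest$group[bad_group][1])
  }
  base <- dirname(path)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(base, manifest$file[i])
    if (!file.exists(f)) stopf("manifest %s line %d: file not found: %s",
                               path, i + 1, manifest$file[i])
    ts <- read_timeseries(f, tr_seconds, manifest$subject_id[i],
                          manifest$group[i])
    if (!is.null(atlas)) {
      if (ncol(ts$values) != atlas$n_regions) {
        stopf("file %s has %d regions but the atlas has %d",
              manifest$file[i], ncol(ts$values), atlas$n_regions)
      }
      if (!is.null(colnames(ts$values)) &&
          !identical(colnames(ts$values), atlas$labels)) {
        stopf("file %s region labels do not match the atlas",
              manifest$file[i])
      }
    }
    ts
  })
  covariates <- manifest[, setdiff(names(manifest), "file"), drop = FALSE]
  structure(list(subjects = subjects, covariates = covariates, spec = NULL),
            class = "fn_cohort")
}

#' Write nodal metrics of many subjects as a tidy table
#'
#' One row per (subject, region, metric, value).
#' @param nodal_list list of `fn_nodal_metrics` named by subject id.
#' @param path file path.
#' @param meta optional metadata comment line.
#' @export
write_nodal_metrics <- function(nodal_list, path, meta = NULL) {
  metrics <- c("degree", "strength", "clustering", "shortest_path_length",
               "global_efficiency", "local_efficiency")
  tidy <- do.call(rbind, lapply(names(nodal_list), function(id) {
    nm <- nodal_list[[id]]
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(subject = id, region = nm$region, metric = m,
                 value = nm[[m]], stringsAsFactors = FALSE)
    }))
  }))
  write_tsv_with_header(tidy, path, meta)
}

#' Write global metrics of many subjects as a tidy table
#'
#' One row per (subject, metric, value).
#' @param global_list list of `fn_global_metrics` named by subject id.
#' @param path file path.
#' @param meta optional metadata comment line.
#' @export
write_global_metrics <- function(global_list, path, meta = NULL) {
  tidy <- do.call(rbind, lapply(names(global_list), function(id) {
    df <- as.data.frame(global_list[[id]])
    data.frame(subject = id, metric = names(df),
               value = as.numeric(df[1, ]), stringsAsFactors = FALSE)
  }))
  write_tsv_with_header(tidy, path, meta)
}

#' Write an NBS component report
#'
#' Per component: a node list, an edge list with t values, the size in
#' links and the corrected p, as a tab-separated table plus a key-value
#' summary block in comments.
#'
#' @param x `fn_nbs`.
#' @param path file path.
#' @param meta optional metadata comment line.
#' @export
write_nbs_report <- function(x, path, meta = NULL) {
  stopifnot(inherits(x, "fn_nbs"))
  rows <- list()
  kv <- c(sprintf("primary_alpha=%g", x$primary_alpha),
          sprintf("n_permutations=%d", x$n_permutations),
          sprintf("seed=%s", format(x$seed)),
          sprintf("n_edges_tested=%d", x$n_edges_tested))
  for (dr in names(x$directions)) {
    comps <- x$directions[[dr]]$components
    kv <- c(kv, sprintf("components_%s=%d", gsub(">", "_gt_", dr),
                        length(comps)))
    for (ci in seq_along(comps)) {
      cp <- comps[[ci]]
      rows[[length(rows) + 1]] <- data.frame(
        direction = dr, component = ci,
        region_i = cp$edges$region_i, region_j = cp$edges$region_j,
        t = cp$edges$t, size_in_links = cp$size_in_links,
        corrected_p = cp$corrected_p, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(0), component = integer(0),
               region_i = character(0), region_j = character(0),
               t = numeric(0), size_in_links = integer(0),
               corrected_p = numeric(0))
  write_tsv_with_header(tab, path, meta = c(meta, kv))
  invisible(path)
}

#' Write a classification report
#'
#' Key-value metrics block (comments), per-fold table, ROC points and
#' selected-feature frequencies.
#'
#' @param x `fn_classification`.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param meta optional metadata comment line.
#' @export
write_classification_report <- function(x, dir, prefix = "classification",
                                        meta = NULL) {
  stopifnot(inherits(x, "fn_classification"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kv <- c(sprintf("families=%s", paste(x$config$families, collapse = "+")),
          sprintf("accuracy=%.6f", x$accuracy),
          sprintf("sensitivity=%.6f", x$sensitivity),
          sprintf("specificity=%.6f", x$specificity),
          sprintf("auc=%.6f", x$auc),
          sprintf("tp=%d tn=%d fp=%d fn=%d", x$confusion$tp, x$confusion$tn,
                  x$confusion$fp, x$confusion$fn),
          sprintf("kernel_weights=%s",
                  paste(sprintf("%s:%.3f", names(x$kernel_weights),
                                x$kernel_weights), collapse = ",")),
          sprintf("selection=%s alpha=%g cost=%g seed=%s",
                  x$config$selection, x$config$selection_alpha,
                  x$config$cost, format(x$config$seed)))
  write_tsv_with_header(x$fold_predictions,
                        file.path(dir, paste0(prefix, "_folds.tsv")),
                        meta = c(meta, kv))
  write_tsv_with_header(x$roc$roc_points,
                        file.path(dir, paste0(prefix, "_roc.tsv")), meta)
  freq <- do.call(rbind, lapply(names(x$selected_frequency), function(f) {
    v <- x$selected_frequency[[f]]
    data.frame(family = f, feature = seq_along(v), frequency = v,
               stringsAsFactors = FALSE)
  }))
  freq <- freq[freq$frequency > 0, , drop = FALSE]
  write_tsv_with_header(freq,
                        file.path(dir, paste0(prefix, "_features.tsv")), meta)
  invisible(dir)
}
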