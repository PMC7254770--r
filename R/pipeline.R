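#' Pipeline configuration
#'
#' Collects every stage toggle, threshold, seed and path of the analysis
#' pipeline in one serializable object. Every stochastic stage has an
#' explicit seed; the configuration round-trips through its YAML
#' serialization unchanged.
#'
#' @param n_group_a,n_group_b synthetic cohort group sizes.
#' @param n_regions,n_volumes,tr_seconds cohort dimensions.
#' @param seed master seed for cohort generation.
#' @param bandpass_low_hz,bandpass_high_hz passband (Hz); `NA` disables
#'   filtering.
#' @param bonferroni_alpha edge-retention level before Bonferroni division.
#' @param negative_policy negative-edge policy for thresholding.
#' @param n_null,null_seed rewired-null ensemble size and seed.
#' @param hub_fraction hub selection fraction.
#' @param hub_ranking `"degree"` or `"strength"`.
#' @param nbs_primary_alpha,nbs_permutations,nbs_seed NBS parameters.
#' @param fdr_q FDR level for nodal comparisons.
#' @param selection_alpha,svm_cost,inner_folds,classifier_seed classifier
#'   parameters.
#' @param selection_placement `"fold"` or `"pooled"`.
#' @param stages character subset of
#'   `c("simulate", "construct", "metrics", "organization", "inference",
#'   "classify")`.
#' @param out_dir output directory.
#' @return list of class `fn_config`.
#' @export
pipeline_config <- function(n_group_a = 64, n_group_b = 66, n_regions = 90,
                            n_volumes = 197, tr_seconds = 3, seed = 1,
                            bandpass_low_hz = 0.01, bandpass_high_hz = 0.1,
                            bonferroni_alpha = 0.05,
                            negative_policy = "positive",
                            n_null = 100, null_seed = 100,
                            hub_fraction = 0.15, hub_ranking = "degree",
                            nbs_primary_alpha = 0.001,
                            nbs_permutations = 5000, nbs_seed = 200,
                            fdr_q = 0.05,
                            selection_alpha = 0.001, svm_cost = 1,
                            inner_folds = 5, classifier_seed = 300,
                            selection_placement = "fold",
                            stages = c("simulate", "construct", "metrics",
                                       "organization", "inference",
                                       "classify"),
                            out_dir = tempfile("funcnet_run_")) {
  cfg <- as.list(environment())
  structure(cfg, class = "fn_config")
}

#' Write / read a pipeline configuration (YAML)
#' @param config `fn_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fn_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "fn_config")
}

#' Hash of the semantically meaningful configuration fields
#'
#' MD5 of the canonical YAML serialization, excluding `out_dir` (a run
#' location, not a parameter).
#' @param config `fn_config`.
#' @return character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "fn_config"))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

log_msg <- function(...) {
  message(sprintf("[funcnet %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Executes, as toggled by `config$stages`: synthetic cohort simulation,
#' band-pass filtering and network construction, global/nodal topological
#' metrics, rich-club + distance organization, group inference (global,
#' nodal FDR, connection classes, NBS, covariate correlations) and MKL-SVM
#' classification. All result tables are written under `config$out_dir`
#' with the configuration hash and seeds in a comment header; the result
#' bundle is returned invisibly.
#'
#' @param config `fn_config`.
#' @param cohort optional precomputed `fn_cohort` (used instead of
#'   simulation when the `simulate` stage is off).
#' @return (invisibly) list with the per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "fn_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  meta <- sprintf("funcnet %s config %s seed %s",
                  as.character(utils::packageVersion("funcnet")),
                  hash, format(config$seed))
  write_config(config, file.path(config$out_dir, "config.yaml"))
  stages <- config$stages
  bundle <- list(config = config, hash = hash)

  run_stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_msg("stage %-12s done in %.1f s", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  if ("simulate" %in% stages) {
    cohort <- run_stage("simulate", {
      spec <- cohort_spec(
        n_group_a = config$n_group_a, n_group_b = config$n_group_b,
        n_regions = config$n_regions, n_volumes = config$n_volumes,
        tr_seconds = config$tr_seconds,
        planted_edges = default_planted_edges(config$n_regions),
        covariate_models = default_covariate_models(config$n_regions),
        seed = config$seed)
      generate_cohort(spec)
    })
  }
  if (is.null(cohort)) stopf("no cohort: enable the simulate stage or supply one")
  bundle$cohort <- cohort
  groups <- vapply(cohort$subjects, `[[`, character(1), "group_label")
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  atlas <- if (config$n_regions == 90) make_default_atlas() else NULL

  if ("construct" %in% stages) {
    bundle$networks <- run_stage("construct", {
      lapply(cohort$subjects, function(s) {
        ts <- if (is.finite(config$bandpass_low_hz)) {
          bandpass_filter(s, config$bandpass_low_hz, config$bandpass_high_hz)
        } else {
          s
        }
        threshold_network(correlation_matrix(ts),
                          alpha = config$bonferroni_alpha,
                          negative_policy = config$negative_policy)
      })
    })
  }

  if ("metrics" %in% stages && !is.null(bundle$networks)) {
    run_stage("metrics", {
      bundle$nodal <- lapply(bundle$networks, nodal_metrics)
      names(bundle$nodal) <- ids
      bundle$global <- lapply(seq_along(bundle$networks), function(i) {
        global_metrics(bundle$networks[[i]], n_null = config$n_null,
                       seed = config$null_seed + i)
      })
      names(bundle$global) <- ids
      write_nodal_metrics(bundle$nodal,
                          file.path(config$out_dir, "nodal_metrics.tsv"), meta)
      write_global_metrics(bundle$global,
                           file.path(config$out_dir, "global_metrics.tsv"),
                           meta)
    })
  }

  if ("organization" %in% stages && !is.null(bundle$networks)) {
    run_stage("organization", {
      hubs <- identify_hubs(bundle$networks, fraction = config$hub_fraction,
                            ranking = config$hub_ranking)
      classes <- lapply(bundle$networks, classify_connections,
                        hub_set = as.character(hubs))
      names(classes) <- ids
      bundle$hubs <- hubs
      bundle$classes <- classes
      summ <- do.call(rbind, lapply(ids, function(id) {
        s <- classes[[id]]$summary; s$subject <- id; s
      }))
      write_tsv_with_header(summ,
                            file.path(config$out_dir, "connection_classes.tsv"),
                            meta)
      if (!is.null(atlas)) {
        bundle$distance <- distance_bins(atlas)
        strat <- lapply(ids, function(id) {
          ec <- classes[[id]]
          st <- stratify_edges(ec$edges, bundle$distance)
          st$edges$subject <- id
          st$edges
        })
        write_tsv_with_header(do.call(rbind, strat),
                              file.path(config$out_dir, "edge_classes.tsv"),
                              meta)
      }
    })
  }

  if ("inference" %in% stages && !is.null(bundle$networks)) {
    run_stage("inference", {
      a <- groups == "A"; b <- groups == "B"
      if (!is.null(bundle$global)) {
        bundle$compare_global <- compare_global(bundle$global[a],
                                                bundle$global[b])
        write_tsv_with_header(as.data.frame(bundle$compare_global),
                              file.path(config$out_dir, "compare_global.tsv"),
                              meta)
      }
      if (!is.null(bundle$nodal)) {
        bundle$compare_nodal <- compare_nodal(bundle$nodal[a],
                                              bundle$nodal[b],
                                              q = config$fdr_q)
        write_tsv_with_header(as.data.frame(bundle$compare_nodal),
                              file.path(config$out_dir, "compare_nodal.tsv"),
                              meta)
      }
      if (!is.null(bundle$classes)) {
        bundle$compare_classes <- compare_connection_classes(
          bundle$classes[a], bundle$classes[b])
        write_tsv_with_header(as.data.frame(bundle$compare_classes),
                              file.path(config$out_dir, "compare_classes.tsv"),
                              meta)
      }
      bundle$nbs <- nbs(bundle$networks[a], bundle$networks[b],
                        primary_alpha = config$nbs_primary_alpha,
                        n_permutations = config$nbs_permutations,
                        seed = config$nbs_seed)
      write_nbs_report(bundle$nbs, file.path(config$out_dir, "nbs.tsv"), meta)
      extra <- setdiff(names(cohort$covariates), c("subject_id", "group"))
      if (length(extra) && !is.null(bundle$nodal)) {
        met <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
        for (cm in default_covariate_models(config$n_regions)) {
          reg_idx <- cm$region
          met[[paste0(cm$metric, ".", cm$region)]] <- vapply(
            seq_along(ids), function(i) {
              nm <- bundle$nodal[[i]]
              col <- switch(cm$metric, strength = nm$strength,
                            global_efficiency = nm$global_efficiency,
                            local_efficiency = nm$local_efficiency,
                            clustering = nm$clustering,
                            shortest_path_length = nm$shortest_path_length)
              idx <- if (is.character(reg_idx)) match(reg_idx, nm$region)
                     else reg_idx
              col[idx]
            }, numeric(1))
        }
        bundle$correlations <- correlate_metrics(met, cohort$covariates)
        write_tsv_with_header(as.data.frame(bundle$correlations),
                              file.path(config$out_dir, "correlations.tsv"),
                              meta)
      }
    })
  }

  if ("classify" %in% stages && !is.null(bundle$networks) &&
      !is.null(bundle$nodal)) {
    run_stage("classify", {
      feats <- build_features(bundle$networks, unname(bundle$nodal), groups)
      bundle$classification <- mkl_svm_loocv(
        feats, selection_alpha = config$selection_alpha,
        cost = config$svm_cost, inner_folds = config$inner_folds,
        selection = config$selection_placement,
        seed = config$classifier_seed)
      write_classification_report(bundle$classification, config$out_dir,
                                  meta = meta)
    })
  }

  invisible(bundle)
}

#' Default planted group effect: bilateral 20th-region pair to a
#' DMN-like set
#'
#' For 90 regions, plants correlation increments from the bilateral
#' parahippocampal regions of the bundled atlas onto six other DMN-like
#' regions; for other sizes, a small clique on the first regions.
#' @param n_regions region count.
#' @param delta increment (default 0.15).
#' @return data frame `i`, `j`, `delta`.
#' @export
default_planted_edges <- function(n_regions = 90, delta = 0.15) {
  if (n_regions == 90) {
    at <- make_default_atlas()
    phg <- which(at$labels %in% c("PHG.L", "PHG.R"))
    targets <- which(at$labels %in% c("PCUN.L", "PCUN.R", "ACG.L", "ACG.R",
                                      "ANG.L", "ANG.R"))
    data.frame(i = rep(phg, each = length(targets)),
               j = rep(targets, times = length(phg)),
               delta = delta)
  } else {
    p <- upper_pairs(min(4, n_regions))
    data.frame(i = p[, 1], j = p[, 2], delta = delta)
  }
}

#' Default planted covariate models
#'
#' An amyloid-like biomarker with a strong negative correlation (-0.67) to
#' the nodal strength of the left parahippocampal region in group B, and a
#' memory-like score with a moderate negative correlation (-0.3) to a
#' cingulate region's local efficiency in group A.
#' @param n_regions region count.
#' @return list of covariate model lists.
#' @export
default_covariate_models <- function(n_regions = 90) {
  if (n_regions != 90) {
    return(list(list(name = "biomarker", metric = "strength", region = 1,
                     target_correlation = -0.67, group_scope = "B")))
  }
  list(
    list(name = "csf_abeta", metric = "strength", region = "PHG.L",
         target_correlation = -0.67, group_scope = "B"),
    list(name = "memory_score", metric = "local_efficiency",
         region = "DCG.L", target_correlation = -0.30, group_scope = "A")
  )
}
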