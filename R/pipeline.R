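# File-level pipeline: read inputs, filter, threshold + cluster, evaluate,
# and write TSV outputs plus a run manifest. The command-line interface at
# inst/cli/funsplit.R is a thin wrapper over these two functions.

#' Run threshold selection and clustering over a dataset on disk
#'
#' Reads embeddings, family map and annotations, applies the requested
#' dataset filters, computes superfamily thresholds from all families,
#' clusters the (by default annotated) families, and writes
#' `thresholds.tsv`, `assignments.tsv` and `manifest.txt` to `out_dir`.
#' Identical inputs and parameters produce byte-identical outputs.
#'
#' @param embeddings_path,family_map_path,annotations_path input files (see
#'   [read_embeddings()], [read_family_map()], [read_annotations()]).
#' @param out_dir output directory, created if missing.
#' @param metric,theta_quantile,n_neighbors,annotated_only see [funsplit()].
#' @param labels_are_ec see [read_annotations()].
#' @param filters named list of [filter_dataset()] switches.
#' @return Invisibly, the [funsplit()] fit.
#' @export
run_cluster <- function(embeddings_path, family_map_path, annotations_path = NULL,
                        out_dir = ".", metric = "euclidean",
                        theta_quantile = 0.5, n_neighbors = 5,
                        annotated_only = !is.null(annotations_path),
                        labels_are_ec = TRUE, filters = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  e <- read_embeddings(embeddings_path)
  fs <- read_family_map(family_map_path)
  ann <- if (!is.null(annotations_path))
    read_annotations(annotations_path, labels_are_ec = labels_are_ec)
  else annotation_table(list())
  if (length(filters)) {
    flt <- do.call(filter_dataset, c(list(fs = fs, ann = ann), filters))
    fs <- flt$families; ann <- flt$annotations
  }
  fit <- funsplit(e, fs, annotations = if (length(ann$labels)) ann else NULL,
                  metric = metric, theta_quantile = theta_quantile,
                  n_neighbors = n_neighbors, annotated_only = annotated_only)
  write_thresholds(fit$thresholds, file.path(out_dir, "thresholds.tsv"))
  write_cluster_assignments(fit$results, file.path(out_dir, "assignments.tsv"))
  manifest <- c(
    paste0("package_version\t", as.character(utils::packageVersion("funsplit"))),
    paste0("embeddings\t", embeddings_path),
    paste0("family_map\t", family_map_path),
    paste0("annotations\t", annotations_path %||% ""),
    paste0("metric\t", metric),
    paste0("theta_quantile\t", format(theta_quantile)),
    paste0("n_neighbors\t", format(n_neighbors)),
    paste0("annotated_only\t", annotated_only),
    paste0("filters\t", paste(names(filters)[unlist(filters)], collapse = ",")),
    paste0("families_clustered\t", length(fit$results)),
    paste0("families_skipped\t", paste(fit$skipped, collapse = ","))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(fit)
}

#' Evaluate cluster assignments: purity, EC spread and random baseline
#'
#' Reads assignments (as written by [run_cluster()] /
#' [write_cluster_assignments()]) plus annotations, and writes to `out_dir`:
#' `purity.tsv` (per-family reports), `summary.txt` (dataset summary with
#' bootstrap CIs), `ec_spread.tsv` (per-label cluster counts, with and
#' without outliers as singleton clusters) and `baseline.tsv` (mean purity
#' of each seeded random-null draw).
#'
#' @param assignments_path path to a cluster-assignments file.
#' @param annotations_path path to the annotation table.
#' @param out_dir output directory.
#' @param labels_are_ec see [read_annotations()].
#' @param impure_only restrict the summary to impure families?
#' @param baseline_draws number of random-null draws (0 to skip).
#' @param n_boot,level,seed bootstrap / null-model seeding.
#' @return Invisibly, a list with `reports`, `summary`, `spread`,
#'   `baseline`.
#' @export
run_evaluate <- function(assignments_path, annotations_path, out_dir = ".",
                         labels_are_ec = TRUE, impure_only = FALSE,
                         baseline_draws = 100, n_boot = 1000, level = 0.95,
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- read_cluster_assignments(assignments_path)
  ann <- read_annotations(annotations_path, labels_are_ec = labels_are_ec)
  unmatched <- setdiff(unlist(lapply(results, clustering_members)),
                       c(names(ann$labels), ann$meta$protein_id))
  # ids absent from the annotation table are legitimate (un-annotated
  # proteins); a wholly disjoint id universe is an input mix-up
  if (length(results) && length(names(ann$labels)) &&
      !length(intersect(unlist(lapply(results, clustering_members)),
                        names(ann$labels))))
    stop("no assignment id matches the annotation table; first unmatched: ",
         paste(utils::head(unmatched, 5L), collapse = ", "), call. = FALSE)
  reports <- do.call(rbind, lapply(results, family_purity, ann = ann))
  rownames(reports) <- NULL
  utils::write.table(as.data.frame(reports), file.path(out_dir, "purity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- dataset_purity_summary(reports, impure_only = impure_only,
                                 n_boot = n_boot, level = level, seed = seed)
  writeLines(utils::capture.output(print(summ)), file.path(out_dir, "summary.txt"))
  spread <- do.call(rbind, lapply(names(results), function(fid) {
    s0 <- ec_cluster_spread(results[[fid]], ann, outliers_as_singletons = FALSE)
    s1 <- ec_cluster_spread(results[[fid]], ann, outliers_as_singletons = TRUE)
    if (!nrow(s0)) return(NULL)
    data.frame(family_id = fid, label = s0$label, n_clusters = s0$n_clusters,
               n_clusters_with_outliers = s1$n_clusters[match(s0$label, s1$label)],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(spread, file.path(out_dir, "ec_spread.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  baseline <- NULL
  if (baseline_draws > 0) {
    fit_like <- structure(list(results = results, annotations = ann),
                          class = "funsplit")
    baseline <- random_baseline_purity(fit_like, nsim = baseline_draws, seed = seed)
    utils::write.table(data.frame(draw = seq_along(baseline),
                                  mean_purity_pct = baseline),
                       file.path(out_dir, "baseline.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(reports = reports, summary = summ, spread = spread,
                 baseline = baseline))
}
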