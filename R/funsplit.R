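# The main fitting function: threshold selection, per-family DBSCAN, purity
# evaluation, and the S3 methods of the fitted object.

#' Sub-cluster functional families by embedding distances
#'
#' Fits the full procedure: (1) for every superfamily, the DBSCAN distance
#' threshold theta is chosen as a quantile (default: the median) of the
#' per-member average within-family distances pooled over *all* its
#' families; (2) each family is clustered with DBSCAN (neighborhood size
#' `n_neighbors`, counting the point itself; strict `<` threshold),
#' splitting it into sub-clusters and outliers; (3) if annotations are
#' supplied, per-family EC purity statistics are computed.
#'
#' By default only families containing at least one annotated protein are
#' clustered (thresholds still use every family), mirroring the typical
#' evaluation setting; set `annotated_only = FALSE` to cluster everything.
#'
#' @param embeddings an [embedding_set()].
#' @param families a [family_set()].
#' @param annotations optional [annotation_table()].
#' @param metric `"euclidean"` (default), `"cosine"` or `"manhattan"`.
#' @param theta_quantile quantile for threshold selection in (0, 1);
#'   0.25/0.75 give the stricter/looser quartile variants.
#' @param n_neighbors neighborhood size: fixed integer >= 2 (default 5) or a
#'   fraction of family size, see [resolve_neighborhood()].
#' @param annotated_only cluster only families with annotated members?
#' @return An object of class `funsplit` with components `thresholds`
#'   (a `threshold_table`), `results` (named list of `family_clustering`),
#'   `purity` (stacked [family_purity()] reports, or `NULL`), `skipped`
#'   (families without a usable threshold), `annotations`, and `params`.
#' @examples
#' sim <- simulate_families(n_superfamilies = 1, families_per_superfamily = 2,
#'                          members_per_component = 6, dimension = 16, seed = 42)
#' fit <- funsplit(sim$embeddings, sim$families, sim$annotations)
#' fit
#' summary(fit, n_boot = 200)
#' @export
funsplit <- function(embeddings, families, annotations = NULL,
                     metric = c("euclidean", "cosine", "manhattan"),
                     theta_quantile = 0.5, n_neighbors = 5,
                     annotated_only = !is.null(annotations)) {
  metric <- match.arg(metric)
  missing <- setdiff(families$protein_id, rownames(embeddings))
  if (length(missing))
    stop("no embedding for mapped protein id(s): ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...", call. = FALSE)
  thresholds <- superfamily_thresholds(embeddings, families,
                                       quantile = theta_quantile, metric = metric)
  fam <- families(families)
  if (annotated_only) {
    if (is.null(annotations))
      stop("annotated_only = TRUE requires an annotation table", call. = FALSE)
    keep <- vapply(fam$members, function(m)
      any(lengths(annotations_of(annotations, m)) > 0L), logical(1))
    fam <- fam[keep, , drop = FALSE]
  }
  results <- list(); skipped <- character(0)
  for (i in seq_len(nrow(fam))) {
    sf <- fam$superfamily_id[i]
    theta <- thresholds$theta[match(sf, thresholds$superfamily_id)]
    if (is.na(theta) || theta <= 0) {
      message("skipping family ", fam$family_id[i], ": no usable threshold for ",
              sf, if (!is.na(theta)) " (theta = 0)")
      skipped <- c(skipped, fam$family_id[i])
      next
    }
    results[[fam$family_id[i]]] <-
      cluster_family(embeddings, fam$members[[i]], theta = theta,
                     n = n_neighbors, metric = metric,
                     family_id = fam$family_id[i])
  }
  purity <- NULL
  if (!is.null(annotations) && length(results)) {
    purity <- do.call(rbind, lapply(results, family_purity, ann = annotations))
    rownames(purity) <- NULL
  }
  structure(list(thresholds = thresholds, results = results, purity = purity,
                 skipped = skipped, annotations = annotations,
                 params = list(metric = metric, theta_quantile = theta_quantile,
                               n_neighbors = n_neighbors,
                               annotated_only = annotated_only),
                 call = match.call()),
            class = "funsplit")
}

#' @export
print.funsplit <- function(x, ...) {
  cat("Embedding-based family sub-clustering\n")
  cat(sprintf("  metric %s, theta quantile %.2f, n = %s\n", x$params$metric,
              x$params$theta_quantile, format(x$params$n_neighbors)))
  cat(sprintf("  %d superfamily threshold(s); %d family(ies) clustered, %d skipped\n",
              nrow(x$thresholds), length(x$results), length(x$skipped)))
  if (length(x$results)) {
    nc <- sum(vapply(x$results, function(r) length(r$clusters), integer(1)))
    no <- sum(vapply(x$results, function(r) length(r$outliers), integer(1)))
    cat(sprintf("  %d cluster(s), %d outlier(s)\n", nc, no))
  }
  if (!is.null(x$purity))
    cat(sprintf("  mean family purity: %.1f%% over %d family(ies) with annotated clusters\n",
                mean(x$purity$purity_pct, na.rm = TRUE),
                sum(!is.na(x$purity$purity_pct))))
  invisible(x)
}

#' Summarize a fitted sub-clustering
#'
#' @param object a [funsplit()] fit with annotations.
#' @param impure_only restrict to impure families?
#' @param n_boot,level,seed bootstrap settings.
#' @param ... unused.
#' @return A `dataset_summary`, see [dataset_purity_summary()].
#' @export
summary.funsplit <- function(object, impure_only = FALSE,
                             n_boot = 1000, level = 0.95, seed = 1, ...) {
  if (is.null(object$purity))
    stop("no purity reports: fit was run without annotations", call. = FALSE)
  dataset_purity_summary(object$purity, impure_only = impure_only,
                         n_boot = n_boot, level = level, seed = seed)
}

#' Draw size-preserving random-clustering nulls from a fit
#'
#' Each simulation replaces every family's partition by a uniformly random
#' one with the identical cluster-size multiset and outlier count
#' (see [random_clustering()]), the null model against which purity gains
#' are judged.
#'
#' @param object a [funsplit()] fit.
#' @param nsim number of null draws.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` named lists of `family_clustering` objects.
#' @export
simulate.funsplit <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(b) {
    res <- lapply(seq_along(object$results), function(i)
      random_clustering(object$results[[i]], seed = seed * 10000L + b * 1000L + i))
    names(res) <- names(object$results)
    res
  })
}

#' Mean purity of random-null draws
#'
#' Convenience wrapper: draws `nsim` random nulls from the fit and returns
#' the across-family mean purity of each draw, for comparison with the
#' fitted clustering's own mean purity.
#'
#' @param object a [funsplit()] fit with annotations.
#' @param nsim number of null draws.
#' @param seed integer seed.
#' @return Numeric vector of length `nsim`.
#' @export
random_baseline_purity <- function(object, nsim = 100, seed = 1) {
  if (is.null(object$annotations))
    stop("fit has no annotations", call. = FALSE)
  nulls <- simulate.funsplit(object, nsim = nsim, seed = seed)
  vapply(nulls, function(draw) {
    rep <- do.call(rbind, lapply(draw, family_purity, ann = object$annotations))
    mean(rep$purity_pct, na.rm = TRUE)
  }, numeric(1))
}

#' Plot purity distribution of a fit
#'
#' Histogram of per-family purity (percentage of annotated clusters that
#' are pure), with the mean marked.
#'
#' @param x a [funsplit()] fit with annotations.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.funsplit <- function(x, ...) {
  if (is.null(x$purity)) stop("fit has no purity reports", call. = FALSE)
  p <- x$purity$purity_pct[!is.na(x$purity$purity_pct)]
  graphics::hist(p, breaks = seq(0, 100, by = 10),
                 main = "Per-family cluster purity",
                 xlab = "Purity (% pure clusters among annotated clusters)", ...)
  graphics::abline(v = mean(p), lty = 2)
  invisible(x)
}
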