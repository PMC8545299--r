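# EC-set purity semantics, per-family purity statistics, dataset summaries
# and the EC-spread over-splitting diagnostic.

#' Canonicalize EC number labels
#'
#' Only EC numbers annotated at all four levels are accepted; partial labels
#' (a trailing dash, a wildcard, fewer than four levels) are rejected and
#' the protein is treated as un-annotated for them. Accepted labels are
#' returned trimmed of surrounding whitespace; level tokens such as `n1`
#' (preliminary ECs) are allowed.
#'
#' @param raw character vector of raw labels.
#' @return Character vector of the same length; rejected labels are `NA`.
#' @export
normalize_ec <- function(raw) {
  x <- trimws(as.character(raw))
  ok <- grepl("^[A-Za-z0-9]+\\.[A-Za-z0-9]+\\.[A-Za-z0-9]+\\.[A-Za-z0-9]+$", x)
  x[!ok] <- NA_character_
  x
}

#' Purity status of a group of proteins
#'
#' A group (a cluster, or a whole family) is judged on its annotated members
#' only. It is `"pure"` iff all annotated members carry *identical* label
#' sets: a group in which every protein has the same two EC numbers is pure
#' (a multifunctional sub-family), while a group with one protein annotated
#' EC1+EC2 and another annotated EC1 alone is impure. With no annotated
#' member the group is `"unannotated"`.
#'
#' @param ids member protein ids.
#' @param ann an [annotation_table()].
#' @return One of `"pure"`, `"impure"`, `"unannotated"`.
#' @export
is_pure <- function(ids, ann) {
  sets <- annotations_of(ann, ids)
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) return("unannotated")
  sets <- lapply(sets, sort)
  first <- sets[[1L]]
  pure <- all(vapply(sets, identical, logical(1), first))
  if (pure) "pure" else "impure"
}

#' Per-family purity statistics
#'
#' Purity of a family is the percentage of its annotated clusters that are
#' pure:  purity = 100 * #pure clusters / #clusters with ECs.  The
#' sequence-weighted analogue counts proteins instead of clusters:
#' sequence purity = 100 * #sequences in pure clusters / #sequences in
#' clusters with ECs (un-annotated members of an annotated cluster count via
#' their cluster membership). Outliers enter neither statistic; their share
#' of the family is reported separately. Families whose clusters are all
#' un-annotated have undefined purity (`NA`) and are excluded from dataset
#' summaries.
#'
#' @param r a `family_clustering`.
#' @param ann an [annotation_table()].
#' @return One-row data frame of class `purity_report` with columns
#'   `family_id`, `n_members`, `n_clusters`, `n_clusters_with_ec`,
#'   `n_pure_clusters`, `purity_pct`, `sequence_purity_pct`, `n_outliers`,
#'   `outlier_fraction`, `distinct_ec_count`, `distinct_ec_set_count`,
#'   `family_status`.
#' @export
family_purity <- function(r, ann) {
  members <- clustering_members(r)
  status <- vapply(r$clusters, is_pure, character(1), ann = ann)
  sizes <- lengths(r$clusters)
  with_ec <- status != "unannotated"
  pure <- status == "pure"
  n_with_ec <- sum(with_ec)
  sets <- annotations_of(ann, members)
  sets <- sets[lengths(sets) > 0L]
  df <- data.frame(
    family_id = r$family_id,
    n_members = length(members),
    n_clusters = length(r$clusters),
    n_clusters_with_ec = n_with_ec,
    n_pure_clusters = sum(pure),
    purity_pct = if (n_with_ec) 100 * sum(pure) / n_with_ec else NA_real_,
    sequence_purity_pct = if (n_with_ec) 100 * sum(sizes[pure]) / sum(sizes[with_ec])
                          else NA_real_,
    n_sequences_with_ec_clusters = sum(sizes[with_ec]),
    n_outliers = length(r$outliers),
    outlier_fraction = length(r$outliers) / length(members),
    distinct_ec_count = length(unique(unlist(sets))),
    distinct_ec_set_count = length(unique(lapply(sets, sort))),
    family_status = is_pure(members, ann),
    stringsAsFactors = FALSE
  )
  class(df) <- c("purity_report", "data.frame")
  df
}

#' Dataset-level purity summary
#'
#' Aggregates per-family purity reports: mean purity across families, the
#' percentage of families split into exclusively pure clusters, the
#' percentage of annotated clusters that are impure, and protein-weighted
#' analogues, each with a percentile bootstrap confidence interval
#' (resampling families).
#'
#' @param reports data frame of stacked [family_purity()] rows.
#' @param impure_only restrict to impure families (those whose members carry
#'   more than one distinct annotation set)?
#' @param n_boot,level,seed bootstrap settings, see [bootstrap_ci()].
#' @return A `dataset_summary` list; see fields in the examples of
#'   [funsplit()].
#' @export
dataset_purity_summary <- function(reports, impure_only = FALSE,
                                   n_boot = 1000, level = 0.95, seed = 1) {
  rep_all <- as.data.frame(reports)
  eligible <- rep_all[!is.na(rep_all$purity_pct), , drop = FALSE]
  if (impure_only)
    eligible <- eligible[eligible$family_status == "impure", , drop = FALSE]
  if (nrow(eligible) == 0L)
    stop("no family with defined purity to summarize", call. = FALSE)
  boot <- function(stat_fun, k) boot_ci(eligible, stat_fun, n_boot, level, seed + k)
  mean_purity <- boot(function(d) mean(d$purity_pct), 1L)
  mean_seq_purity <- boot(function(d) mean(d$sequence_purity_pct), 2L)
  fully_pure <- boot(function(d) 100 * mean(d$purity_pct == 100), 3L)
  pct_impure_clusters <- boot(function(d)
    100 * sum(d$n_clusters_with_ec - d$n_pure_clusters) / sum(d$n_clusters_with_ec), 4L)
  protein_pct_pure <- boot(function(d)
    100 * sum(d$sequence_purity_pct / 100 * d$n_sequences_with_ec_clusters) /
      sum(d$n_sequences_with_ec_clusters), 5L)
  out <- list(
    n_families = nrow(rep_all),
    n_eligible_families = nrow(eligible),
    n_impure_families = sum(rep_all$family_status == "impure"),
    total_clusters = sum(rep_all$n_clusters),
    total_outliers = sum(rep_all$n_outliers),
    mean_outlier_pct = 100 * mean(rep_all$outlier_fraction),
    mean_purity_pct = mean_purity,
    mean_sequence_purity_pct = mean_seq_purity,
    pct_fully_pure_families = fully_pure,
    pct_impure_clusters = pct_impure_clusters,
    protein_pct_in_pure_clusters = protein_pct_pure,
    impure_only = impure_only,
    ci_level = level, n_boot = n_boot, seed = seed
  )
  class(out) <- "dataset_summary"
  out
}

# Bootstrap a statistic of a data frame by resampling its rows (families).
boot_ci <- function(df, stat_fun, n_boot, level, seed) {
  point <- stat_fun(df)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      stat_fun(df[sample.int(nrow(df), replace = TRUE), , drop = FALSE])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  list(point = point, lower = q[1L], upper = q[2L])
}

#' @export
print.dataset_summary <- function(x, ...) {
  fmt <- function(b) sprintf("%.1f%% (CI [%.1f-%.1f%%])", b$point, b$lower, b$upper)
  cat("Dataset purity summary",
      if (x$impure_only) "(impure families only)" else "(all eligible families)", "\n")
  cat(sprintf("  families: %d total, %d with annotated clusters, %d impure\n",
              x$n_families, x$n_eligible_families, x$n_impure_families))
  cat(sprintf("  clusters: %d, outliers: %d (mean outlier share %.1f%%)\n",
              x$total_clusters, x$total_outliers, x$mean_outlier_pct))
  cat("  mean purity:              ", fmt(x$mean_purity_pct), "\n")
  cat("  mean sequence purity:     ", fmt(x$mean_sequence_purity_pct), "\n")
  cat("  fully pure families:      ", fmt(x$pct_fully_pure_families), "\n")
  cat("  impure annotated clusters:", fmt(x$pct_impure_clusters), "\n")
  cat("  proteins in pure clusters:", fmt(x$protein_pct_in_pure_clusters), "\n")
  invisible(x)
}

#' EC-spread over-splitting diagnostic
#'
#' For each label occurring in a family, counts the number of clusters in
#' which it occurs. A clustering that scatters one EC number across many
#' clusters is over-split even if every cluster is pure. Optionally outliers
#' are counted as singleton clusters.
#'
#' @param r a `family_clustering`.
#' @param ann an [annotation_table()].
#' @param outliers_as_singletons count each annotated outlier as a
#'   one-member cluster?
#' @return Data frame with columns `label` and `n_clusters`.
#' @export
ec_cluster_spread <- function(r, ann, outliers_as_singletons = FALSE) {
  groups <- r$clusters
  if (outliers_as_singletons) groups <- c(groups, as.list(r$outliers))
  labs <- lapply(groups, function(g) unique(unlist(annotations_of(ann, g))))
  tab <- table(unlist(labs))
  if (!length(tab))
    return(data.frame(label = character(0), n_clusters = integer(0)))
  data.frame(label = names(tab), n_clusters = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
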