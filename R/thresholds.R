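# Superfamily-specific DBSCAN distance threshold theta, derived from the
# distribution of per-member average within-family distances.

#' Per-member average within-family distances
#'
#' For each family member, the mean distance to all other members of the
#' same family (the diagonal is excluded).
#'
#' @param d a square symmetric distance matrix (e.g. from
#'   [embedding_distances()]).
#' @return Numeric vector, one value per member, named by member id.
#' @export
member_average_distances <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L)
    stop("average distance undefined for a singleton family", call. = FALSE)
  stats::setNames(rowSums(d) / (n - 1L), rownames(d))
}

#' Distance threshold for one superfamily
#'
#' Pools the per-member average within-family distances across all families
#' of a superfamily (each member counted once; singleton families skipped)
#' and returns the requested quantile. The default, the median, picks a
#' cutoff such that half of the superfamily's sequences lie on average
#' within theta of their family co-members. Quantiles are computed with
#' linear interpolation between order statistics.
#'
#' @param dists list of distance matrices, one per family of the superfamily.
#' @param quantile quantile of the pooled averages in (0, 1); 0.25 and 0.75
#'   give the first/third-quartile variants.
#' @return theta, a single nonnegative number.
#' @export
superfamily_threshold <- function(dists, quantile = 0.5) {
  stopifnot(quantile > 0, quantile < 1)
  eligible <- Filter(function(d) nrow(as.matrix(d)) >= 2L, dists)
  if (!length(eligible))
    stop("no family with >= 2 members; threshold undefined", call. = FALSE)
  pooled <- unlist(lapply(eligible, member_average_distances), use.names = FALSE)
  theta <- unname(stats::quantile(pooled, probs = quantile, type = 7))
  if (theta == 0)
    warning("degenerate threshold theta = 0 (identical members)", call. = FALSE)
  theta
}

#' Threshold table for a whole dataset
#'
#' Computes theta per superfamily from every one of its families (including
#' un-annotated ones). Superfamilies with no multi-member family get no
#' threshold and are reported with a message; their families are skipped at
#' clustering time.
#'
#' @param e an [embedding_set()].
#' @param fs a [family_set()].
#' @param quantile see [superfamily_threshold()].
#' @param metric distance metric, see [embedding_distances()].
#' @return A `threshold_table`: data frame with columns `superfamily_id`,
#'   `theta`, `quantile`, `metric`.
#' @export
superfamily_thresholds <- function(e, fs, quantile = 0.5, metric = "euclidean") {
  fam <- families(fs)
  out <- lapply(split(fam, fam$superfamily_id), function(sf) {
    dists <- lapply(sf$members[lengths(sf$members) >= 2L],
                    function(m) embedding_distances(e, m, metric))
    if (!length(dists)) {
      message("superfamily ", sf$superfamily_id[1L],
              ": no family with >= 2 members, no threshold")
      return(NULL)
    }
    data.frame(superfamily_id = sf$superfamily_id[1L],
               theta = superfamily_threshold(dists, quantile),
               quantile = quantile, metric = metric,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  if (is.null(tab))
    tab <- data.frame(superfamily_id = character(0), theta = numeric(0),
                      quantile = numeric(0), metric = character(0))
  rownames(tab) <- NULL
  structure(tab, class = c("threshold_table", "data.frame"))
}

#' Write / read a threshold table as TSV
#' @param tab a `threshold_table` from [superfamily_thresholds()].
#' @param path file path.
#' @return `path` (write) or a `threshold_table` (read).
#' @export
write_thresholds <- function(tab, path) {
  df <- as.data.frame(tab)
  df$theta <- sprintf("%.17g", df$theta)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "numeric",
                                               "numeric", "character"))
  structure(df, class = c("threshold_table", "data.frame"))
}
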