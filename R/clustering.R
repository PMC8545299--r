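# DBSCAN over a within-family distance matrix, with the conventions used
# throughout this package: strict "<" in the neighborhood predicate, a
# neighbor count n that includes the point itself, and deterministic
# border-point assignment. Plus the size-preserving random-clustering null.

#' Construct a family clustering result
#'
#' @param family_id family identifier.
#' @param clusters list of disjoint, non-empty character vectors of member
#'   ids.
#' @param outliers character vector of member ids not in any cluster.
#' @param params list with elements `theta`, `n`, `metric` (provenance).
#' @return An object of class `family_clustering`.
#' @export
family_clustering <- function(family_id, clusters, outliers, params) {
  all_ids <- c(unlist(clusters), outliers)
  if (anyDuplicated(all_ids))
    stop("clusters and outliers must be disjoint", call. = FALSE)
  if (any(lengths(clusters) == 0L))
    stop("empty cluster in clustering result", call. = FALSE)
  structure(list(family_id = family_id, clusters = clusters,
                 outliers = as.character(outliers), params = params),
            class = "family_clustering")
}

#' @export
print.family_clustering <- function(x, ...) {
  cat("Family", x$family_id, "--", length(x$clusters), "cluster(s)",
      sprintf("(sizes %s),", paste(lengths(x$clusters), collapse = ", ")),
      length(x$outliers), "outlier(s)\n")
  cat("  theta =", format(x$params$theta, digits = 4),
      " n =", x$params$n, " metric =", x$params$metric, "\n")
  invisible(x)
}

#' Members of a clustering result
#' @param r a `family_clustering`.
#' @return Character vector of all member ids (clusters then outliers).
#' @export
clustering_members <- function(r) c(unlist(r$clusters), r$outliers)

#' Resolve a neighborhood-size specification
#'
#' The neighborhood size n (the number of neighbors required for a core
#' point, counting the point itself) may be given as a fixed integer >= 2 or
#' as a fraction x in (0, 1) of the family size |F|. Fractions resolve to
#' round(x * |F|) (half away from zero), floored at 2.
#'
#' @param n fixed integer >= 2, or fraction in (0, 1).
#' @param family_size |F|, the number of members.
#' @return Integer n.
#' @export
resolve_neighborhood <- function(n, family_size) {
  stopifnot(length(n) == 1L, is.numeric(n), family_size >= 1L)
  if (n > 0 && n < 1) {
    n <- max(2L, as.integer(floor(n * family_size + 0.5)))
  } else if (n >= 2 && n == as.integer(n)) {
    n <- as.integer(n)
  } else {
    stop("neighborhood must be an integer >= 2 or a fraction in (0, 1)",
         call. = FALSE)
  }
  if (n > family_size)
    warning("neighborhood n = ", n, " exceeds family size ", family_size,
            "; every member will be an outlier", call. = FALSE)
  n
}

#' DBSCAN on a precomputed distance matrix
#'
#' A point p is a core point iff at least `n` points q (counting p itself)
#' satisfy d(p, q) < theta — note the strict inequality. Clusters are the
#' connected components of core points under mutual theta-reachability,
#' plus border points within theta of some core point. Points that are
#' neither are outliers. Members are processed in ascending index order and
#' a border point reachable from several clusters joins the
#' first-discovered one, so results are deterministic.
#'
#' @param d square symmetric distance matrix with member ids as dimnames.
#' @param theta distance threshold, > 0.
#' @param n neighborhood size (integer >= 2, counting the point itself).
#' @param family_id optional family identifier recorded in the result.
#' @return A [family_clustering()].
#' @export
dbscan_cluster <- function(d, theta, n, family_id = "family") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (nrow(d) > 0 && max(abs(d - t(d))) > 1e-9)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (!is.numeric(theta) || theta <= 0) stop("theta must be > 0", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  m <- nrow(d)
  close <- d < theta            # includes self: d(p, p) = 0 < theta
  core <- rowSums(close) >= n
  labels <- integer(m)          # 0 = unassigned / outlier
  k <- 0L
  for (i in seq_len(m)) {
    if (!core[i] || labels[i] != 0L) next
    k <- k + 1L
    queue <- i
    labels[i] <- k
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(close[p, ] & core & labels == 0L)
      labels[nb] <- k
      queue <- c(queue, nb)
    }
  }
  # border points: within theta of a core point; join the first-discovered
  # cluster among those reachable
  for (i in seq_len(m)) {
    if (core[i] || labels[i] != 0L) next
    reach <- labels[close[i, ] & core]
    if (length(reach)) labels[i] <- min(reach)
  }
  clusters <- lapply(seq_len(k), function(j) ids[labels == j])
  family_clustering(family_id, clusters, ids[labels == 0L],
                    params = list(theta = theta, n = n,
                                  metric = attr(d, "metric") %||% "precomputed"))
}

#' Cluster one family under a superfamily threshold
#'
#' Composes [embedding_distances()], [resolve_neighborhood()] and
#' [dbscan_cluster()]. A singleton family yields zero clusters and one
#' outlier.
#'
#' @param e an [embedding_set()].
#' @param members protein ids of the family.
#' @param theta distance threshold (typically from [superfamily_thresholds()]).
#' @param n neighborhood specification, see [resolve_neighborhood()].
#' @param metric distance metric.
#' @param family_id identifier recorded in the result.
#' @return A [family_clustering()].
#' @export
cluster_family <- function(e, members, theta, n = 5,
                           metric = "euclidean", family_id = "family") {
  if (length(members) == 1L)
    return(family_clustering(family_id, list(), members,
                             params = list(theta = theta, n = NA_integer_,
                                           metric = metric)))
  d <- embedding_distances(e, members, metric)
  n_res <- suppressWarnings(resolve_neighborhood(n, length(members)))
  dbscan_cluster(d, theta, n_res, family_id)
}

#' Size-preserving random clustering null
#'
#' Draws a random partition with exactly the cluster-size multiset and
#' outlier count of an observed clustering: the family members are permuted
#' uniformly at random and refilled into the same slots. This is the null
#' model against which purity gains are judged — trivially over-split
#' partitions score high purity, and so does their random counterpart.
#'
#' @param r a `family_clustering`.
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return A `family_clustering` with permuted membership.
#' @export
random_clustering <- function(r, seed) {
  members <- clustering_members(r)
  perm <- with_seed(seed, sample(members))
  sizes <- lengths(r$clusters)
  ends <- cumsum(sizes)
  clusters <- lapply(seq_along(sizes), function(j)
    perm[seq(ends[j] - sizes[j] + 1L, ends[j])])
  outliers <- if (length(r$outliers)) perm[seq(sum(sizes) + 1L, length(perm))]
              else character(0)
  family_clustering(r$family_id, clusters, outliers, r$params)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
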