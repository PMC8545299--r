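# Small in-code fixtures shared across the test files.

# Embedding set from a plain matrix of row vectors.
emb <- function(m, ids = NULL) {
  m <- rbind(m)
  rownames(m) <- ids %||% paste0("P", seq_len(nrow(m)))
  embedding_set(m)
}

# 1-d embedding set from a numeric vector of coordinates.
emb1d <- function(x, ids = paste0("P", seq_along(x))) {
  emb(matrix(x, ncol = 1), ids)
}

# Annotation table from a named list of label vectors, skipping EC
# canonicalization so arbitrary labels pass through.
ann_of <- function(...) annotation_table(list(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

# A clustering result built by hand.
clus <- function(clusters, outliers = character(0), family_id = "FF1",
                 theta = 1, n = 2L, metric = "euclidean") {
  family_clustering(family_id, clusters, outliers,
                    params = list(theta = theta, n = n, metric = metric))
}

# Compare two partitions (lists of id vectors) up to cluster order.
same_partition <- function(a, b) {
  setequal(lapply(a, function(x) sort(x)), lapply(b, function(x) sort(x)))
}

# Random euclidean distance matrix over n points in dim dimensions.
rand_dist <- function(n, dim = 3) {
  x <- matrix(stats::rnorm(n * dim), n)
  rownames(x) <- paste0("P", seq_len(n))
  embedding_distances(embedding_set(x), rownames(x), "euclidean")
}
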