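# Within-family pairwise distance matrices: three embedding metrics plus the
# sequence-identity distance used as a baseline.

#' Pairwise distance matrix over a family's embeddings
#'
#' For members x, y with D-dimensional embeddings:
#' euclidean distance is sqrt(sum_i (x_i - y_i)^2); manhattan is
#' sum_i |x_i - y_i|; cosine is 1 - dot(x, y) / (|x| |y|), so that vectors
#' with identical orientation are at distance 0.
#'
#' @param e an [embedding_set()].
#' @param members ordered protein ids; all must be present in `e`.
#' @param metric `"euclidean"`, `"cosine"` or `"manhattan"`.
#' @return Symmetric numeric matrix with zero diagonal, `members` as
#'   dimnames, and attribute `metric`.
#' @export
embedding_distances <- function(e, members,
                                metric = c("euclidean", "cosine", "manhattan")) {
  metric <- match.arg(metric)
  missing <- setdiff(members, rownames(e))
  if (length(missing))
    stop("no embedding for protein id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- unclass(e)[members, , drop = FALSE]
  if (metric %in% c("euclidean", "manhattan")) {
    d <- as.matrix(stats::dist(x, method = metric))
  } else {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0))
      stop("cosine distance undefined for zero vector(s): ",
           paste(members[nrm == 0], collapse = ", "), call. = FALSE)
    d <- 1 - tcrossprod(x / nrm)
    d[d < 0] <- 0  # clip numerical undershoot
    d[upper.tri(d)] <- t(d)[upper.tri(d)]  # mirror for exact symmetry
    diag(d) <- 0
  }
  dimnames(d) <- list(members, members)
  attr(d, "metric") <- metric
  d
}

#' Convert a pairwise percent-identity matrix to a sequence distance matrix
#'
#' Distance is 1 - PIDE. A matrix given on the 0-100 percent scale (detected
#' by its diagonal of 100) is divided by 100 first.
#'
#' @param pide square symmetric matrix of pairwise percent sequence identity,
#'   as fractions in \[0, 1\] (unit diagonal) or percentages in \[0, 100\].
#' @return Distance matrix with attribute `metric = "sequence"`.
#' @export
sequence_distances <- function(pide) {
  p <- as.matrix(pide)
  if (nrow(p) != ncol(p)) stop("PIDE matrix must be square", call. = FALSE)
  if (all(abs(diag(p) - 100) < 1e-9)) p <- p / 100
  if (any(abs(diag(p) - 1) > 1e-9))
    stop("PIDE matrix diagonal must be 1 (fraction scale) or 100 (percent scale)",
         call. = FALSE)
  if (any(p < 0) || any(p > 1 + 1e-12))
    stop("PIDE entries outside [0, 1] after rescaling", call. = FALSE)
  if (max(abs(p - t(p))) > 1e-9) stop("PIDE matrix must be symmetric", call. = FALSE)
  d <- 1 - p
  d[upper.tri(d)] <- t(d)[upper.tri(d)]
  diag(d) <- 0
  attr(d, "metric") <- "sequence"
  d
}

#' Pairwise percent identity from sequences (convenience helper)
#'
#' Computes PIDE by global pairwise alignment (match +1, mismatch 0, gap
#' open/extend penalties 10/1; identity = matches / alignment length). This
#' is one reasonable PIDE convention, not a canonical one: different
#' alignment parameters or denominators give different values. Intended for
#' small fixture sets; quadratic in the number of sequences.
#'
#' @param path path to an (uncompressed) protein FASTA file.
#' @return A PIDE matrix (fractions in \[0, 1\]) suitable for
#'   [sequence_distances()].
#' @export
pide_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the 'Biostrings' package is required for pide_from_fasta()", call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  n <- length(seqs)
  ids <- sub("\\s.*$", "", names(seqs))
  letters <- Biostrings::AA_ALPHABET
  sm <- matrix(0, length(letters), length(letters), dimnames = list(letters, letters))
  diag(sm) <- 1
  p <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      aln <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[j]], type = "global",
                                           substitutionMatrix = sm,
                                           gapOpening = 10, gapExtension = 1)
      p[i, j] <- p[j, i] <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    }
  }
  dimnames(p) <- list(ids, ids)
  p
}
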