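# Readers and writers for embeddings, family maps, annotation tables and
# cluster assignments, plus the dataset filters applied before clustering.

#' Construct an embedding set
#'
#' An embedding set maps protein identifiers to fixed-length real vectors
#' (language-model embeddings). It is stored as a numeric matrix with one row
#' per protein; row names are the protein identifiers.
#'
#' @param x numeric matrix with unique, non-empty row names and finite entries.
#' @return An object of class `embedding_set` (a validated matrix).
#' @export
embedding_set <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("embeddings must be a numeric matrix", call. = FALSE)
  ids <- rownames(x)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("embedding matrix must have non-empty row names (protein ids)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate protein ids in embedding set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!all(is.finite(x)))
    stop("non-finite embedding components for id(s): ",
         paste(unique(ids[rowSums(!is.finite(x)) > 0]), collapse = ", "), call. = FALSE)
  structure(x, class = c("embedding_set", "matrix", "array"))
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("Embedding set:", nrow(x), "proteins,", ncol(x), "dimensions\n")
  invisible(x)
}

#' Read per-protein embeddings
#'
#' Two on-disk layouts are supported symmetrically: a plain whitespace/tab
#' separated text table (`"tsv"`; one row per protein: id followed by the
#' vector components, no header) and an Arrow/Feather binary table
#' (`"feather"`; an `id` column followed by one column per dimension).
#'
#' @param path path to the file.
#' @param format `"auto"` (by file extension), `"tsv"` or `"feather"`.
#' @return An [embedding_set()].
#' @seealso [write_embeddings()]
#' @export
read_embeddings <- function(path, format = c("auto", "tsv", "feather")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(feather|arrow)$", path)) "feather" else "tsv"
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required to read feather embeddings", call. = FALSE)
    df <- as.data.frame(arrow::read_feather(path))
    if (!"id" %in% names(df)) stop("feather embedding table lacks an 'id' column", call. = FALSE)
    m <- as.matrix(df[setdiff(names(df), "id")])
    dimnames(m) <- list(as.character(df$id), NULL)
    return(embedding_set(m))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no embedding records in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(fields, `[`, character(1), 1L)
  dims <- lengths(fields) - 1L
  if (length(unique(dims)) > 1L) {
    bad <- ids[dims != dims[1L]][1L]
    stop("embedding dimension mismatch: id '", bad, "' has ", dims[ids == bad][1L],
         " components, expected ", dims[1L], call. = FALSE)
  }
  vals <- suppressWarnings(lapply(fields, function(f) as.numeric(f[-1L])))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop("non-numeric embedding component at record ", bad[1L],
         " (id '", ids[bad[1L]], "')", call. = FALSE)
  m <- do.call(rbind, vals)
  rownames(m) <- ids
  embedding_set(m)
}

#' Write per-protein embeddings
#'
#' @param e an [embedding_set()].
#' @param path output path.
#' @param format `"tsv"` or `"feather"` (see [read_embeddings()]).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(e, path, format = c("tsv", "feather")) {
  format <- match.arg(format)
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required to write feather embeddings", call. = FALSE)
    df <- data.frame(id = rownames(e), unclass(e), check.names = FALSE)
    arrow::write_feather(df, path)
    return(invisible(path))
  }
  rows <- vapply(seq_len(nrow(e)), function(i)
    paste(c(rownames(e)[i], sprintf("%.17g", e[i, ])), collapse = "\t"), character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Construct a family set
#'
#' A family set records, for every protein, the functional family it belongs
#' to and that family's superfamily. A protein belongs to exactly one family.
#'
#' @param protein_id,family_id,superfamily_id character vectors of equal length.
#' @return A `family_set`: a data frame with those three columns.
#' @export
family_set <- function(protein_id, family_id, superfamily_id) {
  df <- data.frame(protein_id = as.character(protein_id),
                   family_id = as.character(family_id),
                   superfamily_id = as.character(superfamily_id),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  if (anyDuplicated(df$protein_id))
    stop("protein(s) listed in more than one family: ",
         paste(unique(df$protein_id[duplicated(df$protein_id)]), collapse = ", "),
         call. = FALSE)
  fam <- unique(df[c("family_id", "superfamily_id")])
  if (anyDuplicated(fam$family_id))
    stop("family assigned to more than one superfamily: ",
         paste(fam$family_id[duplicated(fam$family_id)], collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("family_set", "data.frame"))
}

#' @export
print.family_set <- function(x, ...) {
  cat("Family set:", nrow(x), "proteins in", length(unique(x$family_id)),
      "families across", length(unique(x$superfamily_id)), "superfamilies\n")
  invisible(x)
}

#' Split a family set into per-family member lists
#'
#' @param fs a [family_set()].
#' @return A data frame with one row per family (`family_id`,
#'   `superfamily_id`) and a list column `members` of protein-id vectors,
#'   in order of first appearance.
#' @export
families <- function(fs) {
  idx <- split(seq_len(nrow(fs)), fs$family_id)
  idx <- idx[order(vapply(idx, min, integer(1)))]
  data.frame(
    family_id = names(idx),
    superfamily_id = vapply(idx, function(i) fs$superfamily_id[i[1L]], character(1)),
    members = I(lapply(idx, function(i) fs$protein_id[i])),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a protein-to-family map
#'
#' Tab-separated columns `protein_id`, `family_id`, `superfamily_id`
#' (a header row naming them is optional).
#'
#' @param path path to the file.
#' @return A [family_set()].
#' @export
read_family_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(df) < 3L) stop("family map needs 3 tab-separated columns", call. = FALSE)
  if (identical(tolower(df[1L, 1L]), "protein_id")) df <- df[-1L, , drop = FALSE]
  family_set(df[[1L]], df[[2L]], df[[3L]])
}

#' Write a protein-to-family map
#' @param fs a [family_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_map <- function(fs, path) {
  utils::write.table(as.data.frame(fs)[c("protein_id", "family_id", "superfamily_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct an annotation table
#'
#' Maps protein identifiers to sets of function labels (canonical four-level
#' EC numbers, or arbitrary labels such as ligand codes), with optional
#' per-label evidence flags and per-protein metadata flags.
#'
#' @param labels named list: protein id -> character vector of labels.
#' @param evidence optional named list parallel to `labels`: per-label
#'   evidence codes (`""` where none).
#' @param meta optional data frame with column `protein_id` and logical flag
#'   columns (e.g. `multi_segment`, `single_domain`).
#' @return An `annotation_table`.
#' @export
annotation_table <- function(labels, evidence = NULL, meta = NULL) {
  stopifnot(is.list(labels))
  if (length(labels) && (is.null(names(labels)) || any(names(labels) == "")))
    stop("labels must be a named list keyed by protein id", call. = FALSE)
  keep <- lengths(labels) > 0L
  labels <- labels[keep]
  if (!is.null(evidence)) evidence <- evidence[names(evidence) %in% names(labels)]
  structure(list(labels = labels, evidence = evidence, meta = meta),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("Annotation table:", length(x$labels), "annotated proteins,",
      length(unique(unlist(x$labels))), "distinct labels\n")
  invisible(x)
}

#' Look up the label sets of a group of proteins
#'
#' @param ann an [annotation_table()].
#' @param ids protein identifiers.
#' @return Named list of label vectors; proteins without annotations get
#'   `character(0)`.
#' @export
annotations_of <- function(ann, ids) {
  out <- ann$labels[match(ids, names(ann$labels))]
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  names(out) <- ids
  out
}

#' Read an annotation table
#'
#' Tab-separated columns: `protein_id`, comma-separated labels, then
#' optionally comma-separated per-label evidence codes and logical flag
#' columns `multi_segment` and `single_domain`. Multiple rows for one protein
#' union their label sets. When `labels_are_ec` is `TRUE` labels are
#' canonicalized with [normalize_ec()]; labels rejected there (partial EC
#' numbers) are dropped with a message and the protein is treated as
#' un-annotated for them.
#'
#' @param path path to the file.
#' @param labels_are_ec canonicalize labels as four-level EC numbers?
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, labels_are_ec = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          comment.char = "#", blank.lines.skip = TRUE)
  if (identical(tolower(df[1L, 1L]), "protein_id")) {
    hdr <- tolower(unlist(df[1L, ]))
    df <- df[-1L, , drop = FALSE]
  } else {
    hdr <- c("protein_id", "labels", "evidence", "multi_segment", "single_domain")[seq_len(ncol(df))]
  }
  names(df) <- hdr
  labels <- list(); evidence <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$protein_id[i]
    labs <- trimws(strsplit(df$labels[i], ",", fixed = TRUE)[[1L]])
    labs <- labs[nzchar(labs)]
    evs <- if (!is.null(df$evidence) && nzchar(df$evidence[i])) {
      e <- trimws(strsplit(df$evidence[i], ",", fixed = TRUE)[[1L]])
      length(e) <- length(labs); e[is.na(e)] <- ""
      e
    } else rep("", length(labs))
    if (labels_are_ec) {
      norm <- normalize_ec(labs)
      if (anyNA(norm))
        message("dropping non-canonical EC label(s) for ", id, ": ",
                paste(labs[is.na(norm)], collapse = ", "))
      evs <- evs[!is.na(norm)]
      labs <- norm[!is.na(norm)]
    }
    if (!length(labs)) next
    prev <- labels[[id]]
    new <- !(labs %in% prev)
    labels[[id]] <- c(prev, labs[new])
    evidence[[id]] <- c(evidence[[id]], evs[new])
  }
  meta <- NULL
  flags <- intersect(c("multi_segment", "single_domain"), names(df))
  if (length(flags)) {
    meta <- unique(data.frame(protein_id = df$protein_id, stringsAsFactors = FALSE))
    for (fl in flags)
      meta[[fl]] <- as.logical(toupper(df[[fl]][match(meta$protein_id, df$protein_id)]))
  }
  annotation_table(labels, evidence, meta)
}

#' Write an annotation table
#' @param ann an [annotation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  ids <- names(ann$labels)
  lab <- vapply(ann$labels, paste, character(1), collapse = ",")
  ev <- if (!is.null(ann$evidence))
    vapply(ids, function(i) paste(ann$evidence[[i]], collapse = ","), character(1))
  else rep("", length(ids))
  df <- data.frame(protein_id = ids, labels = lab, evidence = ev,
                   stringsAsFactors = FALSE)
  if (!is.null(ann$meta)) {
    m <- ann$meta[match(ids, ann$meta$protein_id), , drop = FALSE]
    for (fl in setdiff(names(ann$meta), "protein_id")) df[[fl]] <- m[[fl]]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean-pool a per-residue embedding matrix
#'
#' Collapses an L x D matrix of per-residue language-model representations to
#' one fixed-length D-vector by averaging over residue positions.
#'
#' @param m numeric matrix, one row per residue.
#' @return Numeric vector of length `ncol(m)`.
#' @export
mean_pool <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0L) stop("cannot pool an empty residue matrix", call. = FALSE)
  colMeans(m)
}

#' Apply the dataset filters used before clustering
#'
#' Filters are applied in a fixed order: member-level removals first
#' (multi-segment proteins, non-experimental labels), then removal of orphan
#' families (a single remaining member), then superfamily selection. The
#' result never contains an empty family.
#'
#' @param fs a [family_set()].
#' @param ann an [annotation_table()].
#' @param drop_multi_segment remove proteins flagged `multi_segment` (their
#'   embeddings span multiple discontinuous segments).
#' @param drop_orphans remove families left with a single member.
#' @param require_impure_superfamily keep only superfamilies containing at
#'   least one impure family (members with differing annotation sets).
#' @param experimental_only keep only labels carrying the experimental
#'   evidence code `ECO:0000269`.
#' @param single_domain_only keep only families whose every member is flagged
#'   `single_domain`.
#' @return `list(families = <family_set>, annotations = <annotation_table>)`.
#' @export
filter_dataset <- function(fs, ann,
                           drop_multi_segment = FALSE,
                           drop_orphans = FALSE,
                           require_impure_superfamily = FALSE,
                           experimental_only = FALSE,
                           single_domain_only = FALSE) {
  df <- as.data.frame(fs)
  need_flag <- function(flag) {
    if (is.null(ann$meta) || !flag %in% names(ann$meta))
      stop("filter requires flag column '", flag, "' in annotation metadata",
           call. = FALSE)
  }
  # member-level removals
  if (drop_multi_segment) {
    need_flag("multi_segment")
    ms <- ann$meta$protein_id[isTRUE_vec(ann$meta$multi_segment)]
    df <- df[!df$protein_id %in% ms, , drop = FALSE]
  }
  if (experimental_only) {
    if (is.null(ann$evidence))
      stop("filter requires per-label evidence codes in the annotation table",
           call. = FALSE)
    labels <- ann$labels
    for (id in names(labels)) {
      keep <- grepl("ECO:0000269", ann$evidence[[id]] %||% rep("", length(labels[[id]])),
                    fixed = TRUE)
      labels[[id]] <- labels[[id]][keep]
    }
    ev <- lapply(labels, function(l) rep("ECO:0000269", length(l)))
    ann <- annotation_table(labels, evidence = ev, meta = ann$meta)
  }
  if (single_domain_only) {
    need_flag("single_domain")
    sd_ok <- ann$meta$protein_id[isTRUE_vec(ann$meta$single_domain)]
    fam_ok <- tapply(df$protein_id %in% sd_ok, df$family_id, all)
    df <- df[df$family_id %in% names(fam_ok)[fam_ok], , drop = FALSE]
  }
  # orphan-family removal (empty families are always dropped)
  size <- table(df$family_id)
  min_size <- if (drop_orphans) 2L else 1L
  df <- df[df$family_id %in% names(size)[size >= min_size], , drop = FALSE]
  # superfamily selection
  if (require_impure_superfamily) {
    fam <- split(df$protein_id, df$family_id)
    impure <- vapply(fam, function(ids) is_pure(ids, ann) == "impure", logical(1))
    sf_imp <- unique(df$superfamily_id[df$family_id %in% names(fam)[impure]])
    df <- df[df$superfamily_id %in% sf_imp, , drop = FALSE]
  }
  list(families = family_set(df$protein_id, df$family_id, df$superfamily_id),
       annotations = ann)
}

isTRUE_vec <- function(x) !is.na(x) & x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write cluster assignments
#'
#' Tab-separated rows `protein_id`, `family_id`, `cluster_label` (an integer
#' starting at 1, or the literal `outlier`). Header comment lines record the
#' clustering parameters (theta, n, metric) of every family so that
#' [read_cluster_assignments()] reproduces the partition exactly.
#'
#' @param results list of `family_clustering` objects (see [dbscan_cluster()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_assignments <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# funsplit cluster assignments", con)
  for (r in results)
    writeLines(sprintf("# params\tfamily_id=%s\ttheta=%.17g\tn=%d\tmetric=%s",
                       r$family_id, r$params$theta, r$params$n, r$params$metric), con)
  writeLines("protein_id\tfamily_id\tcluster_label", con)
  for (r in results) {
    for (k in seq_along(r$clusters))
      writeLines(paste(r$clusters[[k]], r$family_id, k, sep = "\t"), con)
    if (length(r$outliers))
      writeLines(paste(r$outliers, r$family_id, "outlier", sep = "\t"), con)
  }
  invisible(path)
}

#' Read cluster assignments written by [write_cluster_assignments()]
#'
#' @param path path to the file.
#' @return List of `family_clustering` objects, one per family.
#' @export
read_cluster_assignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  par_lines <- grep("^# params\t", lines, value = TRUE)
  params <- list()
  for (pl in par_lines) {
    kv <- strsplit(sub("^# params\t", "", pl), "\t")[[1L]]
    kv <- strsplit(kv, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                            vapply(kv, `[`, character(1), 1L))
    params[[vals[["family_id"]]]] <- list(theta = as.numeric(vals[["theta"]]),
                                          n = as.integer(vals[["n"]]),
                                          metric = vals[["metric"]])
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) && startsWith(body[1L], "protein_id")) body <- body[-1L]
  out <- list()
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    for (fid in unique(parts[, 2L])) {
      rows <- parts[parts[, 2L] == fid, , drop = FALSE]
      lab <- rows[, 3L]
      ks <- sort(unique(as.integer(lab[lab != "outlier"])))
      out[[fid]] <- family_clustering(
        family_id = fid,
        clusters = lapply(ks, function(k) rows[lab == as.character(k), 1L]),
        outliers = rows[lab == "outlier", 1L],
        params = params[[fid]] %||% list(theta = NA_real_, n = NA_integer_,
                                         metric = NA_character_))
    }
  }
  out
}
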