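# Seeded generator of superfamilies with planted functional sub-structure:
# each family is a mixture of well-separated isotropic Gaussian components in
# embedding space, each component tied to one EC-number set, with
# configurable rates of multifunctional components, withheld annotations and
# isolated noise points.

#' Simulate families with planted functional sub-structure
#'
#' Per family, `components_per_family` component centers are drawn on a
#' sphere of radius `component_separation` and rejected until all pairwise
#' center distances are at least 1.3 x `component_separation`; members are
#' the center plus isotropic Gaussian noise scaled so that the *expected
#' embedding-space distance* between two members of the same component is
#' `within_component_spread` (per-coordinate standard deviation
#' spread / sqrt(2 D)). Defining the spread as a distance makes the
#' separation/spread ratio — the hardness knob — independent of the
#' embedding dimension.
#' Each component carries a distinct synthetic four-level EC number (from
#' disjoint integer blocks per superfamily); with probability
#' `multi_ec_rate` a component carries two EC numbers, identically on all
#' its members — a pure multifunctional group. With probability
#' `unannotated_rate` a member's labels are withheld. Noise points are
#' placed at radius 4 x separation (hence at least 3 x separation from
#' every center) and left un-annotated.
#'
#' The defaults (separation 20 at spread 1, 128 dimensions) emulate the
#' regime in which functional sub-groups are cleanly separable in embedding
#' space; shrink the separation/spread ratio to make recovery harder.
#'
#' @param n_superfamilies number of superfamilies.
#' @param families_per_superfamily families in each superfamily.
#' @param components_per_family planted components per family (>= 1).
#' @param members_per_component proteins per component.
#' @param dimension embedding dimension D.
#' @param component_separation minimum distance between component centers.
#' @param within_component_spread expected distance between two members of
#'   the same component (isotropic Gaussian noise).
#' @param multi_ec_rate probability a component is multifunctional (two ECs).
#' @param unannotated_rate probability a member's labels are withheld.
#' @param noise_point_rate expected isolated noise points per family, as a
#'   fraction of its planted members.
#' @param seed integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_families`: `embeddings`
#'   ([embedding_set()]), `families` ([family_set()]), `annotations`
#'   ([annotation_table()]), and `truth`, a data frame with the planted
#'   component, EC set and noise flag of every protein.
#' @export
simulate_families <- function(n_superfamilies = 2,
                              families_per_superfamily = 4,
                              components_per_family = 2,
                              members_per_component = 10,
                              dimension = 128,
                              component_separation = 20,
                              within_component_spread = 1,
                              multi_ec_rate = 0.1,
                              unannotated_rate = 0.1,
                              noise_point_rate = 0.05,
                              seed = 1) {
  stopifnot(components_per_family >= 1, members_per_component >= 1,
            component_separation > 0, within_component_spread > 0,
            multi_ec_rate >= 0, multi_ec_rate <= 1,
            unannotated_rate >= 0, unannotated_rate <= 1,
            noise_point_rate >= 0, noise_point_rate <= 1)
  coord_sd <- within_component_spread / sqrt(2 * dimension)
  with_seed(seed, {
    emb <- list(); ids <- character(0)
    fam_rows <- list(); truth_rows <- list()
    labels <- list()
    for (s in seq_len(n_superfamilies)) {
      sf_id <- sprintf("SF%02d", s)
      for (f in seq_len(families_per_superfamily)) {
        fam_id <- sprintf("%s_FF%02d", sf_id, f)
        centers <- draw_separated_centers(components_per_family, dimension,
                                          component_separation)
        multi <- stats::runif(components_per_family) < multi_ec_rate
        p <- 0L
        for (k in seq_len(components_per_family)) {
          ec_set <- sprintf("%d.%d.%d.%d", s, f, k, 1L)
          if (multi[k]) ec_set <- c(ec_set, sprintf("%d.%d.%d.%d", s, f, k, 2L))
          for (j in seq_len(members_per_component)) {
            p <- p + 1L
            pid <- sprintf("%s_P%04d", fam_id, p)
            vec <- centers[k, ] + stats::rnorm(dimension, 0, coord_sd)
            emb[[pid]] <- vec
            fam_rows[[pid]] <- c(pid, fam_id, sf_id)
            withheld <- stats::runif(1) < unannotated_rate
            if (!withheld) labels[[pid]] <- ec_set
            truth_rows[[pid]] <- data.frame(
              protein_id = pid, family_id = fam_id, superfamily_id = sf_id,
              component = k, ec_set = paste(ec_set, collapse = ","),
              annotated = !withheld, is_noise = FALSE,
              stringsAsFactors = FALSE)
          }
        }
        n_noise <- stats::rbinom(1L, components_per_family * members_per_component,
                                 noise_point_rate)
        for (j in seq_len(n_noise)) {
          p <- p + 1L
          pid <- sprintf("%s_P%04d", fam_id, p)
          u <- stats::rnorm(dimension)
          emb[[pid]] <- 4 * component_separation * u / sqrt(sum(u^2))
          fam_rows[[pid]] <- c(pid, fam_id, sf_id)
          truth_rows[[pid]] <- data.frame(
            protein_id = pid, family_id = fam_id, superfamily_id = sf_id,
            component = NA_integer_, ec_set = "", annotated = FALSE,
            is_noise = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    m <- do.call(rbind, emb)
    fam <- do.call(rbind, fam_rows)
    meta <- data.frame(protein_id = rownames(m),
                       multi_segment = FALSE, single_domain = TRUE,
                       stringsAsFactors = FALSE)
    structure(list(
      embeddings = embedding_set(m),
      families = family_set(fam[, 1L], fam[, 2L], fam[, 3L]),
      annotations = annotation_table(labels,
                                     evidence = lapply(labels, function(l)
                                       rep("ECO:0000269", length(l))),
                                     meta = meta),
      truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
    ), class = "synthetic_families")
  })
}

# Draw k centers on a sphere of radius `sep` with all pairwise distances
# >= 1.3 * sep; rejection-sampled. Random directions are near-orthogonal in
# high dimension (typical pairwise gap sep * sqrt(2)), so the 1.3 factor
# mostly rejects near-collinear draws; it keeps the *minimum* center gap
# comparable to the typical one, so a single separation knob controls
# hardness.
draw_separated_centers <- function(k, dimension, sep, max_tries = 1000L) {
  if (k == 1L) return(matrix(0, 1L, dimension))
  for (try in seq_len(max_tries)) {
    u <- matrix(stats::rnorm(k * dimension), k)
    u <- sep * u / sqrt(rowSums(u^2))
    if (min(stats::dist(u)) >= 1.3 * sep) return(u)
  }
  stop("cannot place ", k, " centers at separation ", sep, " in ",
       dimension, " dimensions", call. = FALSE)
}

#' @export
print.synthetic_families <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$truth), "proteins,",
      length(unique(x$truth$family_id)), "families,",
      length(unique(x$truth$superfamily_id)), "superfamilies,",
      sum(x$truth$is_noise), "noise points\n")
  invisible(x)
}

#' Write a synthetic dataset to the package's on-disk formats
#'
#' Emits exactly the files the readers consume, so simulated data can feed
#' the file-based pipeline unchanged.
#'
#' @param x a `synthetic_families` object.
#' @param dir output directory (created if missing).
#' @return Named character vector of the paths written.
#' @export
write_synthetic <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(embeddings = file.path(dir, "embeddings.tsv"),
             families = file.path(dir, "families.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_embeddings(x$embeddings, paths[["embeddings"]])
  write_family_map(x$families, paths[["families"]])
  write_annotations(x$annotations, paths[["annotations"]])
  utils::write.table(x$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
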