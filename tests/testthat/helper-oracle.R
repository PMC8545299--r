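# Independent reference oracle for density-based clustering: runs
# scikit-learn's DBSCAN (metric="precomputed") on a batch of instances via a
# single python call. Used to cross-check the package's own implementation;
# never used by the package itself.

oracle_py <- '
import sys, json
import numpy as np
from sklearn.cluster import DBSCAN
data = json.load(sys.stdin)
out = []
for inst in data:
    d = np.array(inst["d"], dtype=float)
    m = DBSCAN(eps=inst["eps"], min_samples=int(inst["min_samples"]),
               metric="precomputed").fit(d)
    out.append({"labels": [int(v) for v in m.labels_],
                "core": [int(v) for v in m.core_sample_indices_]})
json.dump(out, sys.stdout)
'

# instances: list of list(d = matrix, eps = numeric, min_samples = integer).
# Returns a list of list(labels = 0-based cluster labels (-1 = outlier),
# core = 0-based core indices).
run_dbscan_oracle <- function(instances) {
  script <- tempfile(fileext = ".py")
  writeLines(oracle_py, script)
  input <- tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(instances, function(i)
      list(d = i$d, eps = jsonlite::unbox(i$eps),
           min_samples = jsonlite::unbox(i$min_samples))),
    input, digits = NA)
  out <- system2("python", script, stdout = TRUE, stdin = input)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# Agreement check between a family_clustering and an oracle result, up to
# cluster relabeling. Core points and their partition must agree exactly;
# outlier sets must agree exactly; a border point may legitimately sit in
# any cluster owning a core point within theta of it (the tie rule differs
# between implementations), so each side's assignment is checked for
# admissibility.
clusterings_agree <- function(r, oracle, d, theta) {
  n <- nrow(d)
  ours <- integer(n)                      # 0 = outlier
  for (k in seq_along(r$clusters))
    ours[as.integer(r$clusters[[k]])] <- k
  theirs <- vapply(oracle$labels, function(l) l + 1L, integer(1))  # -1 -> 0
  our_core <- which(vapply(seq_len(n), function(i)
    sum(d[i, ] < theta) >= r$params$n, logical(1)))
  their_core <- vapply(oracle$core, function(i) i + 1L, integer(1))
  if (!setequal(our_core, their_core)) return(FALSE)
  if (!setequal(which(ours == 0L), which(theirs == 0L))) return(FALSE)
  # identical partition restricted to core points
  co <- sort(our_core)
  if (length(co) > 1L) {
    for (a in seq_along(co)) for (b in seq_along(co)) {
      same_ours <- ours[co[a]] == ours[co[b]]
      same_theirs <- theirs[co[a]] == theirs[co[b]]
      if (same_ours != same_theirs) return(FALSE)
    }
  }
  # border points: both assignments must be admissible
  border <- setdiff(which(ours > 0L), co)
  for (i in border) {
    reach_ours <- unique(ours[intersect(which(d[i, ] < theta), co)])
    if (!(ours[i] %in% reach_ours)) return(FALSE)
    reach_theirs <- unique(theirs[intersect(which(d[i, ] < theta), co)])
    if (!(theirs[i] %in% reach_theirs)) return(FALSE)
  }
  TRUE
}
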