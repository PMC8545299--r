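test_that("EC labels are canonicalized to four full levels", {
  expect_equal(normalize_ec("1.1.1.1"), "1.1.1.1")
  expect_equal(normalize_ec(" 2.3.4.5 "), "2.3.4.5")
  expect_equal(normalize_ec("7.2.2.19"), "7.2.2.19")
  expect_equal(normalize_ec("1.1.1.n3"), "1.1.1.n3")  # preliminary ECs allowed
  expect_true(is.na(normalize_ec("1.1.1.-")))
  expect_true(is.na(normalize_ec("1.1.1")))
  expect_true(is.na(normalize_ec("1.1.*.*")))
  expect_true(is.na(normalize_ec("")))
  expect_equal(normalize_ec(c("1.1.1.1", "2.2.2.-")), c("1.1.1.1", NA))
})

test_that("purity compares full annotation sets, not individual ECs", {
  ann <- ann_of(A = c("1.1.1.1", "2.2.2.2"), B = c("2.2.2.2", "1.1.1.1"),
                C = "1.1.1.1", D = "2.2.2.2", E = c("1.1.1.1", "2.2.2.2"))
  # all members share the same two ECs: a pure multifunctional group
  expect_equal(is_pure(c("A", "B"), ann), "pure")
  # one member EC1, another EC2: impure
  expect_equal(is_pure(c("C", "D"), ann), "impure")
  # EC1+EC2 member next to an EC1-only member: impure (conservative rule)
  expect_equal(is_pure(c("E", "C"), ann), "impure")
  # judged on annotated members only; none annotated -> unannotated
  expect_equal(is_pure(c("X", "Y"), ann), "unannotated")
  expect_equal(is_pure(c("A", "B", "X"), ann), "pure")
})

test_that("family purity implements the cluster and sequence percentages", {
  # 4 clusters, 3 annotated, 2 of the annotated pure -> 66.67%
  ann <- ann_of(a1 = "1.1.1.1", a2 = "1.1.1.1",
                b1 = "2.2.2.2",
                c1 = "3.3.3.3", c2 = "4.4.4.4")
  r <- clus(list(c("a1", "a2"), c("b1", "u1"), c("c1", "c2"), c("u2", "u3")))
  rep1 <- family_purity(r, ann)
  expect_equal(rep1$n_clusters, 4L)
  expect_equal(rep1$n_clusters_with_ec, 3L)
  expect_equal(rep1$n_pure_clusters, 2L)
  expect_equal(rep1$purity_pct, 200 / 3)

  # sequence purity: pure clusters of sizes 5 and 3, impure of size 2,
  # unannotated of size 10 -> 8 / 10 = 80%
  ann2 <- ann_of(p1 = "1.1.1.1", q1 = "2.2.2.2", x1 = "3.3.3.3", x2 = "4.4.4.4")
  r2 <- clus(list(c("p1", paste0("pu", 1:4)),        # pure, size 5
                  c("q1", paste0("qu", 1:2)),        # pure, size 3
                  c("x1", "x2"),                     # impure, size 2
                  paste0("nu", 1:10)))               # unannotated, size 10
  rep2 <- family_purity(r2, ann2)
  expect_equal(rep2$sequence_purity_pct, 80)
  expect_equal(rep2$n_sequences_with_ec_clusters, 10L)

  # every annotated cluster pure -> 100
  r3 <- clus(list(c("a1", "a2"), c("b1")))
  expect_equal(family_purity(r3, ann)$purity_pct, 100)

  # outliers enter neither numerator nor denominator, only their own share
  r4 <- clus(list(c("a1", "a2")), outliers = c("b1", "u9"))
  rep4 <- family_purity(r4, ann)
  expect_equal(rep4$purity_pct, 100)
  expect_equal(rep4$outlier_fraction, 0.5)

  # no annotated cluster: purity undefined
  r5 <- clus(list(c("u1", "u2")))
  expect_true(is.na(family_purity(r5, ann)$purity_pct))
})

test_that("splitting into singletons trivially maximizes purity", {
  ann <- ann_of(a = "1.1.1.1", b = "2.2.2.2", c = "3.3.3.3", d = "1.1.1.1")
  whole <- clus(list(c("a", "b", "c", "d")))
  expect_equal(family_purity(whole, ann)$purity_pct, 0)
  split <- clus(as.list(c("a", "b", "c", "d")))
  expect_equal(family_purity(split, ann)$purity_pct, 100)
})

test_that("merging pure clusters behaves according to their EC sets", {
  ann <- ann_of(a1 = "1.1.1.1", a2 = "1.1.1.1", b1 = "1.1.1.1",
                c1 = "2.2.2.2", d1 = "3.3.3.3")
  base <- clus(list(c("a1", "a2"), "b1", "c1", "d1"))
  p0 <- family_purity(base, ann)$purity_pct
  # identical EC sets: merging cannot decrease purity
  merged_same <- clus(list(c("a1", "a2", "b1"), "c1", "d1"))
  expect_gte(family_purity(merged_same, ann)$purity_pct, p0)
  # different EC sets: merging strictly decreases purity
  merged_diff <- clus(list(c("a1", "a2"), "b1", c("c1", "d1")))
  expect_lt(family_purity(merged_diff, ann)$purity_pct, p0)
})

test_that("purity arithmetic is label-agnostic", {
  ec <- ann_of(a = "1.1.1.1", b = "1.1.1.1", c = "2.2.2.2")
  lig <- ann_of(a = "HEM", b = "HEM", c = "ZN")
  r <- clus(list(c("a", "b"), c("c", "z")))
  expect_equal(family_purity(r, lig)$purity_pct, family_purity(r, ec)$purity_pct)
  expect_equal(family_purity(r, lig)$sequence_purity_pct,
               family_purity(r, ec)$sequence_purity_pct)
})

test_that("EC spread counts clusters per label, optionally with outliers", {
  ann <- ann_of(a = "1.1.1.1", b = "1.1.1.1", c = "2.2.2.2", o = "1.1.1.1",
                d = "3.3.3.3", e = "3.3.3.3", f = "3.3.3.3")
  r <- clus(list(c("a", "c", "d"), c("b", "e"), "f"), outliers = "o")
  s0 <- ec_cluster_spread(r, ann)
  expect_equal(s0$n_clusters[s0$label == "2.2.2.2"], 1L)
  expect_equal(s0$n_clusters[s0$label == "1.1.1.1"], 2L)
  expect_equal(s0$n_clusters[s0$label == "3.3.3.3"], 3L)
  s1 <- ec_cluster_spread(r, ann, outliers_as_singletons = TRUE)
  expect_equal(s1$n_clusters[s1$label == "1.1.1.1"], 3L)
  expect_equal(s1$n_clusters[s1$label == "3.3.3.3"], 3L)
})

test_that("dataset summaries aggregate family reports with bootstrap CIs", {
  ann <- ann_of(a1 = "1.1.1.1", a2 = "1.1.1.1", b1 = "2.2.2.2", b2 = "3.3.3.3")
  pure_fam <- family_purity(clus(list(c("a1", "a2"))), ann)
  impure_fam <- family_purity(clus(list(c("b1", "b2")), family_id = "FF2"), ann)

  s <- dataset_purity_summary(rbind(pure_fam, pure_fam), n_boot = 50)
  expect_equal(s$mean_purity_pct$point, 100)
  expect_equal(s$pct_fully_pure_families$point, 100)

  s2 <- dataset_purity_summary(rbind(pure_fam, impure_fam), n_boot = 50)
  expect_equal(s2$mean_purity_pct$point, 50)
  expect_equal(s2$pct_fully_pure_families$point, 50)
  expect_equal(s2$pct_impure_clusters$point, 50)
  expect_true(s2$mean_purity_pct$lower <= s2$mean_purity_pct$point)
  expect_true(s2$mean_purity_pct$upper >= s2$mean_purity_pct$point)

  # planted purities: mean equals hand-computed mean and lies inside its CI
  set.seed(41)
  planted <- do.call(rbind, lapply(1:10, function(i) {
    k <- sample(2:5, 1)          # clusters in this family
    pure <- sample(0:k, 1)       # planted number of pure clusters
    labels <- list(); clusters <- list()
    for (j in seq_len(k)) {
      ids <- sprintf("f%d_c%d_%d", i, j, 1:2)
      # pure cluster: both members share a label; impure: two labels
      labels[[ids[1]]] <- sprintf("1.1.%d.%d", i, j)
      labels[[ids[2]]] <- if (j <= pure) sprintf("1.1.%d.%d", i, j)
                          else sprintf("2.2.%d.%d", i, j)
      clusters[[j]] <- ids
    }
    r <- family_purity(clus(clusters, family_id = paste0("FF", i)),
                       annotation_table(labels))
    expect_equal(r$purity_pct, 100 * pure / k)
    r
  }))
  s3 <- dataset_purity_summary(planted, n_boot = 200, seed = 7)
  expect_equal(s3$mean_purity_pct$point, mean(planted$purity_pct))
  expect_gte(mean(planted$purity_pct), s3$mean_purity_pct$lower)
  expect_lte(mean(planted$purity_pct), s3$mean_purity_pct$upper)

  # impure-only restriction and the empty-eligible error
  s4 <- dataset_purity_summary(rbind(pure_fam, impure_fam), impure_only = TRUE,
                               n_boot = 50)
  expect_equal(s4$n_eligible_families, 1L)
  unann <- family_purity(clus(list(c("z1", "z2"))), ann)
  expect_error(dataset_purity_summary(unann, n_boot = 10), "no family")
})
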