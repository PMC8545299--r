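test_that("generation is deterministic and internally consistent", {
  cfg <- list(n_superfamilies = 1, families_per_superfamily = 2,
              members_per_component = 6, dimension = 16, seed = 77)
  a <- do.call(simulate_families, cfg)
  b <- do.call(simulate_families, cfg)
  expect_identical(a$embeddings, b$embeddings)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotations$labels, b$annotations$labels)

  # truth, family map and annotations agree
  expect_setequal(a$truth$protein_id, a$families$protein_id)
  expect_setequal(rownames(a$embeddings), a$families$protein_id)
  expect_true(all(names(a$annotations$labels) %in% a$truth$protein_id))
  annotated <- a$truth$protein_id[a$truth$annotated]
  expect_setequal(names(a$annotations$labels), annotated)
  expect_false(any(a$truth$is_noise & a$truth$annotated))
})

test_that("noise points are isolated and multifunctional components are pure", {
  sim <- simulate_families(n_superfamilies = 1, families_per_superfamily = 3,
                           members_per_component = 5, dimension = 16,
                           multi_ec_rate = 1, noise_point_rate = 0.3, seed = 5)
  # every component's members share an identical two-EC set
  tr <- sim$truth[!sim$truth$is_noise & sim$truth$annotated, ]
  for (key in unique(paste(tr$family_id, tr$component))) {
    ids <- tr$protein_id[paste(tr$family_id, tr$component) == key]
    sets <- unique(lapply(sim$annotations$labels[ids], sort))
    expect_length(sets, 1L)
    expect_length(sets[[1]], 2L)
  }
  # noise points lie at >= 3 x separation from every planted member
  noise <- sim$truth$protein_id[sim$truth$is_noise]
  expect_gt(length(noise), 0L)
  for (nid in noise) {
    fam <- sim$truth$family_id[sim$truth$protein_id == nid]
    others <- sim$truth$protein_id[sim$truth$family_id == fam &
                                   !sim$truth$is_noise]
    d <- embedding_distances(sim$embeddings, c(nid, others))
    expect_gt(min(d[1, -1]), 3 * 20 - 3)  # separation 20, spread slack
  }
})

test_that("planted components are recovered exactly at high separation", {
  for (seed in 1:20) {
    sim <- simulate_families(n_superfamilies = 1, families_per_superfamily = 3,
                             members_per_component = 8, dimension = 32,
                             component_separation = 20,
                             within_component_spread = 1, seed = seed)
    fit <- funsplit(sim$embeddings, sim$families, sim$annotations)
    for (fid in names(fit$results)) {
      r <- fit$results[[fid]]
      tr <- sim$truth[sim$truth$family_id == fid, ]
      # adjusted agreement with the planted components is exactly 1
      got <- integer(nrow(tr))
      names(got) <- tr$protein_id
      for (k in seq_along(r$clusters)) got[r$clusters[[k]]] <- k
      planted <- ifelse(tr$is_noise, 0L, tr$component)
      expect_equal(mclust::adjustedRandIndex(got[tr$protein_id], planted), 1)
      # and every annotated recovered cluster is pure
      p <- fit$purity$purity_pct[fit$purity$family_id == fid]
      expect_equal(p, 100)
    }
  }
})

test_that("withholding all annotations leaves families unevaluable", {
  sim <- simulate_families(n_superfamilies = 1, families_per_superfamily = 2,
                           members_per_component = 5, dimension = 16,
                           unannotated_rate = 1, seed = 3)
  expect_length(sim$annotations$labels, 0L)
  fit <- funsplit(sim$embeddings, sim$families, annotated_only = FALSE)
  expect_null(fit$purity)
  rep <- do.call(rbind, lapply(fit$results, family_purity,
                               ann = sim$annotations))
  expect_true(all(is.na(rep$purity_pct)))
  expect_error(dataset_purity_summary(rep, n_boot = 10), "no family")
})

test_that("mean purity degrades as separation shrinks relative to spread", {
  ratios <- c(20, 3, 1)
  mean_purity <- vapply(ratios, function(ratio) {
    mean(vapply(1:5, function(seed) {
      sim <- simulate_families(n_superfamilies = 1, families_per_superfamily = 3,
                               members_per_component = 6, dimension = 16,
                               component_separation = ratio,
                               within_component_spread = 1,
                               noise_point_rate = 0, unannotated_rate = 0,
                               seed = seed)
      fit <- funsplit(sim$embeddings, sim$families, sim$annotations)
      mean(fit$purity$purity_pct, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_purity) <= 0))
  expect_equal(mean_purity[1], 100)
})

test_that("embedding clustering beats the random null at moderate separation", {
  sim <- simulate_families(n_superfamilies = 1, families_per_superfamily = 4,
                           members_per_component = 6, dimension = 16,
                           component_separation = 5, within_component_spread = 1,
                           seed = 11)
  fit <- funsplit(sim$embeddings, sim$families, sim$annotations)
  obs <- mean(fit$purity$purity_pct, na.rm = TRUE)
  rand <- random_baseline_purity(fit, nsim = 30, seed = 2)
  expect_gt(obs, mean(rand))
})
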