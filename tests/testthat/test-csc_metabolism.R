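test_that("perfectly separated histogram clusters exactly", {
  voi <- suv_voi(rep(c(3, 6, 9), each = 5))
  p <- cluster_suv_histogram(voi)
  expect_equal(p$centroids, c(3, 6, 9))
  expect_equal(p$sizes, c(5L, 5L, 5L))
  expect_equal(p$wcss, 0)
  expect_equal(sort(unique(p$labels)), 0:2)
  # labels follow ascending centroids: SUV 9 voxels are cluster 2
  expect_true(all(p$labels[voi$suv_values == 9] == 2))
})

test_that("three distinct values give singleton clusters", {
  p <- cluster_suv_histogram(suv_voi(c(2.5, 2.6, 9.0)))
  expect_equal(p$centroids, c(2.5, 2.6, 9.0))
  expect_equal(p$sizes, c(1L, 1L, 1L))
})

test_that("degenerate histograms are rejected with the distinct count", {
  expect_error(cluster_suv_histogram(suv_voi(rep(3, 10))), "1 distinct")
  expect_error(cluster_suv_histogram(suv_voi(rep(c(3, 7), 5))), "2 distinct")
})

test_that("exact DP is WCSS-optimal against 50 Lloyd restarts", {
  set.seed(11)
  voi <- suv_voi(mixture_suvs(c(80, 70, 50)))
  dp <- cluster_suv_histogram(voi, method = "exact-dp")
  lloyd <- vapply(1:50, function(s)
    cluster_suv_histogram(voi, method = "lloyd", seed = s)$wcss, numeric(1))
  expect_lte(dp$wcss, min(lloyd) + 1e-9)
})

test_that("exact DP is invariant under voxel permutation; Lloyd reproducible under seed", {
  set.seed(5)
  x <- mixture_suvs(c(30, 30, 30))
  p1 <- cluster_suv_histogram(suv_voi(x))
  perm <- sample(length(x))
  p2 <- cluster_suv_histogram(suv_voi(x[perm]))
  expect_equal(p2$centroids, p1$centroids)
  expect_equal(p2$wcss, p1$wcss)
  expect_equal(p2$labels, p1$labels[perm])
  l1 <- cluster_suv_histogram(suv_voi(x), method = "lloyd", seed = 99)
  l2 <- cluster_suv_histogram(suv_voi(x), method = "lloyd", seed = 99)
  expect_identical(l1, l2)
})

test_that("binned mode snaps values to bin centres before clustering", {
  x <- c(3.01, 3.04, 3.08, 6.02, 6.07, 9.01, 9.06, 9.09)
  p <- cluster_suv_histogram(suv_voi(x), bin_width = 0.1)
  expect_equal(p$centroids, c(3.05, 6.05, 9.05), tolerance = 1e-12)
  expect_equal(p$wcss, 0, tolerance = 1e-12)
})

test_that("CSC parameters measure the highest-centroid cluster", {
  voi <- suv_voi(c(rep(3, 5), rep(6, 5), rep(9, 5)))
  p <- cluster_suv_histogram(voi)
  csc <- csc_parameters(voi, p)
  expect_equal(csc$mtv_csc, 5 * 0.064)
  expect_equal(csc$tlg_csc, 45 * 0.064)            # 2.88
  expect_equal(csc$csc_proportion, 100 * 5 / 15)   # 33.33%
})

test_that("cluster volumes and TLG contributions conserve MTV and TLG", {
  set.seed(21)
  for (rep in 1:10) {
    voi <- suv_voi(mixture_suvs(c(40, 30, 20), sd = runif(1, 0.1, 1.5)))
    p <- cluster_suv_histogram(voi)
    conv <- conventional_parameters(voi, voi)
    vols <- sapply(0:2, function(l) sum(p$labels == l) * voi$voxel_volume)
    tlgs <- sapply(0:2, function(l) sum(voi$suv_values[p$labels == l]) * voi$voxel_volume)
    expect_equal(sum(vols), conv$mtv)
    expect_equal(sum(tlgs), conv$tlg)
    csc <- csc_parameters(voi, p)
    expect_lte(csc$mtv_csc, conv$mtv)
    expect_lte(csc$tlg_csc, conv$tlg)
    expect_gt(csc$csc_proportion, 0)
    expect_lt(csc$csc_proportion, 100)
  }
})

test_that("conventional parameters follow the count and sum identities", {
  voi <- suv_voi(rep(4, 10))
  conv <- conventional_parameters(voi, voi)
  expect_equal(conv$mtv, 0.64)
  expect_equal(conv$tlg, 2.56)
  expect_equal(conv$suv_max, 4)
  one <- suv_voi(2.5)
  c1 <- conventional_parameters(one, one)
  expect_equal(c1$mtv, 0.064)
  expect_equal(c1$tlg, 0.16)
  # TLG equals mean SUV x MTV
  set.seed(3)
  voi2 <- suv_voi(runif(33, 2.5, 12))
  c2 <- conventional_parameters(voi2, voi2)
  expect_equal(c2$tlg, mean(voi2$suv_values) * c2$mtv)
})

test_that("patient-level MTVcsc is the maximum across lesions", {
  expect_equal(patient_level_mtvcsc(c(primary = 2.8, axillary_ln = 0.5)),
               list(mtv_csc = 2.8, lesion = "primary"))
  expect_equal(patient_level_mtvcsc(c(primary = 0.9))$mtv_csc, 0.9)
  expect_equal(patient_level_mtvcsc(c(primary = 1.0, ln = 1.9))$lesion, "ln")
  expect_error(patient_level_mtvcsc(numeric(0)), "no lesions")
})

test_that("well-separated mixtures recover the CSC volume within 2 voxels", {
  # component means >= 3 SUV apart, SD <= 0.3: recovery in >= 95% of replicates
  set.seed(101)
  hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    n_csc <- sample(10:40, 1)
    voi <- suv_voi(mixture_suvs(c(60, 50, n_csc), means = c(3, 6, 9), sd = 0.3))
    p <- cluster_suv_histogram(voi)
    err <- abs(sum(p$labels == 2) - n_csc) * voi$voxel_volume
    hits <- hits + (err <= 2 * voi$voxel_volume)
  }
  expect_gte(hits / n_rep, 0.95)
})
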