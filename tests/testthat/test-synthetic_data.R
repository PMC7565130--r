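test_that("phantom truth is self-consistent with the emitted volume", {
  spec <- phantom_spec(counts = c(60, 40, 14), seed = 9)
  ph <- generate_phantom(spec)
  vol <- ph$volume$data
  vv <- ph$volume$voxel_volume
  all_idx <- rbind(ph$truth$differentiated, ph$truth$mixed, ph$truth$csc) + 1L
  expect_equal(anyDuplicated(all_idx), 0)          # compartments disjoint
  suvs <- vol[all_idx]
  avid <- suvs >= 2.5
  expect_equal(ph$truth$mtv, sum(avid) * vv)
  expect_equal(ph$truth$tlg, sum(suvs[avid]) * vv)
  expect_equal(ph$truth$suv_max, max(suvs))
  csc_suv <- vol[ph$truth$csc + 1L]
  expect_equal(ph$truth$mtv_csc, sum(csc_suv >= 2.5) * vv)
  expect_equal(ph$truth$tlg_csc, sum(csc_suv[csc_suv >= 2.5]) * vv)
})

test_that("phantom generation is deterministic under seed and honours SD 0", {
  spec <- phantom_spec(seed = 4)
  expect_identical(generate_phantom(spec)$volume$data,
                   generate_phantom(spec)$volume$data)
  exact <- phantom_spec(sds = c(0, 0, 0), background_sd = 0, seed = 4)
  ph <- generate_phantom(exact)
  tumor_suvs <- unique(ph$volume$data[rbind(ph$truth$differentiated,
                                            ph$truth$mixed, ph$truth$csc) + 1L])
  expect_setequal(tumor_suvs, c(3, 5.5, 9))
})

test_that("a 14-voxel CSC core yields truth MTVcsc 0.896 cm^3", {
  spec <- phantom_spec(counts = c(60, 40, 14), sds = c(0.2, 0.2, 0.2), seed = 12)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$mtv_csc, 14 * 0.064)       # all draws clear SUV 2.5
  voi <- segment_fixed_threshold(ph$volume, ph$truth$seed_voxel)
  expect_equal(nrow(voi$voxel_indices), ph$truth$n_above_threshold)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(means = c(5, 4, 9)), "increasing")
  expect_error(phantom_spec(counts = c(-1, 5, 5)), "> 0")
  expect_error(phantom_spec(shape = c(4, 4, 4), counts = c(40, 40, 40)), "capacity")
})

test_that("blob placement also yields disjoint compartments of the right size", {
  spec <- phantom_spec(shape = c(24, 24, 24), counts = c(50, 30, 12),
                       placement = "blobs", seed = 5)
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$truth$csc), 12)
  expect_equal(nrow(ph$truth$mixed), 30)
  all_idx <- rbind(ph$truth$differentiated, ph$truth$mixed, ph$truth$csc)
  expect_equal(anyDuplicated(all_idx), 0)
})

test_that("end-to-end recovery is exact for noiseless phantoms and tight for separated ones", {
  exact <- end_to_end_recovery(phantom_spec(sds = c(0, 0, 0), background_sd = 0,
                                            seed = 2))
  expect_equal(unname(exact$errors), c(0, 0, 0))
  sep <- end_to_end_recovery(phantom_spec(means = c(3, 5.5, 9),
                                          sds = c(0.2, 0.2, 0.2), seed = 2))
  expect_false(sep$ambiguous_separation)
  expect_lte(sep$errors[["mtv_csc"]], 2 * sep$voxel_volume)
  overlap <- end_to_end_recovery(phantom_spec(means = c(4, 4.5, 5), seed = 2))
  expect_true(overlap$ambiguous_separation)
})

test_that("cohort generation is deterministic and matches the schema", {
  spec <- cohort_spec(seed = 6)
  co <- generate_cohort(spec)
  expect_identical(co, generate_cohort(spec))
  expect_equal(nrow(co), 120)
  expect_true(all(c("patient_id", "subtype", "mtv_csc", "pcr", "dfs_months",
                    "relapse_event", "er_status", "nac_regimen") %in% names(co)))
  expect_equal(sum(co$subtype == "her2_positive"), 57)
  expect_equal(sum(co$subtype == "luminal"), 38)
  expect_equal(sum(co$pcr[co$subtype == "luminal"]), 0)   # pCR rate 0 by design
  expect_true(all(co$mtv_csc > 0))
  expect_true(all(co$mtv_csc <= co$mtv + 1e-9))
  expect_true(all(co$dfs_months > 0))
})

test_that("cohort marginals converge to the spec at n = 10,000", {
  big <- cohort_spec(n = c(her2_positive = 10000, triple_negative = 10000,
                           luminal = 1000),
                     seed = 14)
  co <- generate_cohort(big)
  # pCR rates within 1% of the stratum rates
  expect_lt(abs(mean(co$pcr[co$subtype == "her2_positive"]) - 16 / 57), 0.01)
  expect_lt(abs(mean(co$pcr[co$subtype == "triple_negative"]) - 6 / 25), 0.01)
  # response-group MTVcsc medians at the published values
  expect_lt(abs(median(co$mtv_csc[co$pcr]) - 0.9), 0.1)
  expect_lt(abs(median(co$mtv_csc[!co$pcr]) - 2.8), 0.1)
})
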