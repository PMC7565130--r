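#!/usr/bin/env Rscript
# Step 2 — lesion parameter extraction on the simulated phantoms.
#
# For each phantom: segment at the fixed SUV 2.5 threshold from the hottest
# voxel, delineate the 40%-of-SUVmax volume, partition the VOI's SUV
# histogram into 3 clusters by exact DP k-means, and measure conventional
# (SUVmax, MTV, TLG, MTV40%, TLG40%) and CSC (MTVcsc, TLGcsc, CSC%)
# parameters. Errors against the generator's ground truth quantify recovery;
# the overlapping phantom illustrates the regime where compartments are not
# separable in SUV and cluster boundaries are a partition of convenience.

suppressPackageStartupMessages(library(petcsc))
cfg <- pipeline_config(seed = 20260928L)

rows <- list()
for (nm in c("separated", "noiseless", "overlapping")) {
  truth <- jsonlite::read_json(sprintf("results/phantoms/%s_truth.json", nm),
                               simplifyVector = TRUE)
  out <- run_lesion(cfg, sprintf("results/phantoms/%s.nii.gz", nm),
                    seeds = truth$seed_voxel, labels = "primary",
                    patient_id = nm)
  stopifnot(out$status == "ok")
  p <- out$parameters
  p$truth_mtv_csc <- truth$mtv_csc
  p$mtv_csc_error <- abs(p$mtv_csc - truth$mtv_csc)
  rows[[nm]] <- p
  cat(sprintf("%-11s MTVcsc %.3f (truth %.3f, err %.3f cm^3), CSC%% %.1f, TLG %.1f\n",
              nm, p$mtv_csc, truth$mtv_csc, p$mtv_csc_error,
              p$csc_proportion, p$tlg))
}
params <- do.call(rbind, rows)
write.csv(params, "results/lesion_parameters.csv", row.names = FALSE)
cat(sprintf("well-separated recovery error: %.3f cm^3 (<= 2 voxels = 0.128 cm^3)\n",
            params$mtv_csc_error[params$patient_id == "separated"]))
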