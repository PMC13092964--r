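#!/usr/bin/env Rscript
# Builds the 17-group mass-balance model: published per-group inputs plus a
# reconstructed diet matrix (the published model's diet composition is not
# public). Writes the ready-to-balance model directory and the
# reconstruction calibration table under results/.

library(reefweb)
dir.create("results", showWarnings = FALSE)
seed <- 1L

fx <- core_fixture(seed = seed)
write_model(fx$model, "results/model")

calib <- data.frame(
  group = fx$groups$name,
  TL_published = fx$groups$TL_ref,
  TL_reconstructed = unname(fx$reconstruction$tl_achieved),
  EE_published = fx$groups$EE_ref,
  EE_reconstructed = unname(fx$reconstruction$ee_achieved))
write.csv(calib, "results/diet_reconstruction.csv", row.names = FALSE)

message("Diet reconstruction (seed ", seed, "): max TL residual = ",
        signif(fx$reconstruction$tl_residual, 3),
        " (contract: < 0.1), objective = ",
        signif(fx$reconstruction$objective, 3))
print(calib, digits = 3, row.names = FALSE)
message("Model directory written to results/model/ ",
        "(groups.csv, diet.csv, detritus_fate.csv).")
message("NOTE: the diet matrix is a synthetic calibration artefact fitted ",
        "to the published TL and EE columns, not survey data.")
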