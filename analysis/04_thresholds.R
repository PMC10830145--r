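#!/usr/bin/env Rscript
# Threshold searches: the clustered glutamatergic input count needed for a
# dendritic up-state, the same count under the low-Ra variant, the number
# of distributed GABA synapses needed to tip a just-subthreshold cluster,
# and the NMDA-knockout control.

library(spnsim)
dir.create("results", showWarnings = FALSE)

model <- default_model(seed = 1)
th <- run_experiment("thresholds", model = model, out_dir = "results")
print(th)
cat(sprintf("Up-state threshold: %d clustered glutamatergic inputs;\n",
            th$threshold[th$family == "glutamate"]))
cat(sprintf("%d GABA synapses (12-distal-dendrite mode, 10 ms lead) tip a\n",
            th$threshold[th$family == "gaba12"]))
cat("cluster one input short of threshold into a dendritic spike.\n")

s2 <- run_experiment("s2_ra_variant", model = model, out_dir = "results")
cat(sprintf("Low-Ra variant (100 Ohm cm, AMPA/NMDA x1.6): threshold %d.\n",
            s2$glut_threshold))

ko <- run_experiment("s4_nmda_ko", model = model, out_dir = "results")
cat(sprintf("NMDA knockout: off-site GABA lead no longer generates a spike (quarterdrop %.1f ms).\n",
            ko$quarterdrop))
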