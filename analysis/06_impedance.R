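#!/usr/bin/env Rscript
# Local input impedance at 10 Hz versus GABA-A conductance load: shunting
# is strictly local. On-site synapses collapse the local impedance while
# off-site synapses depolarize without much local impedance change (Kir
# closure partly offsetting the added conductance).

library(spnsim)
dir.create("results", showWarnings = FALSE)

model <- default_model(seed = 1)
z <- run_experiment("fig8_impedance", model = model, out_dir = "results")
z[-1] <- round(z[-1], 2)
print(z)

z0 <- z$impedance_MOhm[z$mode == "onsite" & z$n_syn == 0]
on12 <- z$impedance_MOhm[z$mode == "onsite" & z$n_syn == 12]
off12 <- z$impedance_MOhm[z$mode == "offsite" & z$n_syn == 12]
cat(sprintf(paste0(
  "At the common 12-synapse setting: on-site impedance falls %.0f%%\n",
  "(%.0f -> %.0f MOhm) while off-site falls only %.0f%%.\n"),
  100 * (1 - on12 / z0), z0, on12, 100 * (1 - off12 / z0)))
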