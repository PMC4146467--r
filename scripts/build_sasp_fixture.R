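#!/usr/bin/env Rscript
# Regenerates the bundled SASP truth-table fixture from the programmatic
# definition in R/sasp.R. Run from the repository root.
for (f in list.files("R", full.names = TRUE)) source(f)
net <- sasp_reconstruction()
dir <- "inst/extdata/sasp_synthetic"
unlink(dir, recursive = TRUE)
save_network(net, dir)
writeLines(c(
  "Synthetic reconstruction of the 21-node speract-activated signaling",
  "pathway (SASP) logical network. These truth tables were rebuilt from the",
  "published wiring diagram and electrophysiological narrative of the",
  "pathway; they are NOT a transcription of the original supplementary",
  "tables. Structure (node set, arities, regulator sets, 432-row Ca table)",
  "follows the published description; the dynamical fine print is this",
  "package's own reconstruction. See ?sasp_reconstruction and the package",
  "vignette for the rule-by-rule rationale."
), file.path(dir, "README"))
cat("wrote", length(list.files(dir)), "files to", dir, "\n")
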