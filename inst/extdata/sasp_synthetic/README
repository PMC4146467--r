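Synthetic reconstruction of the 21-node speract-activated signaling
pathway (SASP) logical network. These truth tables were rebuilt from the
published wiring diagram and electrophysiological narrative of the
pathway; they are NOT a transcription of the original supplementary
tables. Structure (node set, arities, regulator sets, 432-row Ca table)
follows the published description; the dynamical fine print is this
package's own reconstruction. See ?sasp_reconstruction and the package
vignette for the rule-by-rule rationale.
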