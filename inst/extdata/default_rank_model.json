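{"weights":{"pair_energy":-3.74727265115402,"torsion_energy":-0.787621594083845},"bias":0,"center":{"pair_energy":-332.201576714803,"torsion_energy":-0.794675060243191},"scale":{"pair_energy":103.998474163753,"torsion_energy":34.2804165944722},"C":1,"meta":{"seed":20260901,"n_pairs":1470,"train_pair_accuracy":0.961904761904762},"format_version":1}
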