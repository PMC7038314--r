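{"format":"gaitseg-layout","version":"1.0","feet":{"left":{"foot_length_mm":260,"sensors":[{"site":"heel","x_ml_mm":-0,"y_ap_mm":31.2},{"site":"midfoot_lateral","x_ml_mm":-30,"y_ap_mm":104},{"site":"met1","x_ml_mm":25,"y_ap_mm":187.2},{"site":"met3","x_ml_mm":-0,"y_ap_mm":182},{"site":"met5","x_ml_mm":-25,"y_ap_mm":176.8},{"site":"hallux","x_ml_mm":18,"y_ap_mm":228.8},{"site":"toe2","x_ml_mm":-0,"y_ap_mm":234},{"site":"toe5","x_ml_mm":-22,"y_ap_mm":234}]},"right":{"foot_length_mm":260,"sensors":[{"site":"heel","x_ml_mm":0,"y_ap_mm":31.2},{"site":"midfoot_lateral","x_ml_mm":30,"y_ap_mm":104},{"site":"met1","x_ml_mm":-25,"y_ap_mm":187.2},{"site":"met3","x_ml_mm":0,"y_ap_mm":182},{"site":"met5","x_ml_mm":25,"y_ap_mm":176.8},{"site":"hallux","x_ml_mm":-18,"y_ap_mm":228.8},{"site":"toe2","x_ml_mm":0,"y_ap_mm":234},{"site":"toe5","x_ml_mm":22,"y_ap_mm":234}]}}}
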