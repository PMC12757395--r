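segment,composite_region
ctx-lh-superiorfrontal,Frontal cerebral cortex
ctx-rh-superiorfrontal,Frontal cerebral cortex
ctx-lh-rostralmiddlefrontal,Frontal cerebral cortex
ctx-lh-superiortemporal,Temporal cerebral cortex
ctx-rh-superiortemporal,Temporal cerebral cortex
wm-lh-superiorfrontal,Frontal white matter
wm-rh-superiorfrontal,Frontal white matter
wm-lh-superiortemporal,Temporal white matter
wm-rh-superiortemporal,Temporal white matter
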