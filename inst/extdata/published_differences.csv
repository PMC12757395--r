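region,diff,ci_low,ci_high,p
Frontal cerebral cortex,-0.5,-0.9,0.0,0.052
Frontal white matter,-0.4,-1.4,0.6,0.412
Temporal cerebral cortex,-0.6,-1.2,0.0,0.035
Temporal white matter,0.8,-0.1,1.7,0.078
Parietal cerebral cortex,0.3,-0.4,1.0,0.472
Parietal white matter,2.4,1.5,3.3,<0.001
Occipital cerebral cortex,0.4,-0.8,1.5,0.522
Occipital white matter,0.4,-1.6,2.4,0.679
Entorhinal cerebral cortex,-0.4,-1.2,0.3,0.273
Entorhinal white matter,0.5,-0.7,1.6,0.424
Insular cerebral cortex,-0.5,-1.3,0.2,0.175
Insular white matter,3.4,1.8,5.0,<0.001
Cingulate cerebral cortex,-0.5,-1.0,0.1,0.106
Cingulate white matter,0.8,-0.7,2.3,0.281
Basal ganglia,0.7,-1.7,3.2,0.567
Limbic structures,-0.6,-1.1,-0.1,0.027
Choroid plexus,-1.2,-3.6,1.1,0.304
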