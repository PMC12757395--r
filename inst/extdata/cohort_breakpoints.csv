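region,cohort,psi,ci_low,ci_high,r2
Frontal cerebral cortex,REF,0.9,0.7,1.2,0.36
Frontal white matter,REF,3.4,2.7,4.0,0.03
Temporal cerebral cortex,REF,0.7,0.5,1.0,0.35
Temporal white matter,REF,2.1,1.6,2.7,0.09
Parietal cerebral cortex,REF,1.5,1.1,1.9,0.29
Parietal white matter,REF,3.4,2.5,4.2,0.03
Occipital cerebral cortex,REF,1.0,0.5,1.5,0.28
Occipital white matter,REF,2.6,1.5,3.6,0.07
Entorhinal cerebral cortex,REF,0.3,-0.1,0.7,0.65
Entorhinal white matter,REF,2.0,1.1,2.8,0.22
Insular cerebral cortex,REF,0.6,0.3,0.9,0.69
Insular white matter,REF,2.3,0.7,3.9,0.06
Cingulate cerebral cortex,REF,0.7,0.5,0.9,0.53
Cingulate white matter,REF,2.2,1.3,3.0,0.06
Basal ganglia,REF,2.2,0.8,3.5,0.02
Limbic structures,REF,0.6,0.3,0.8,0.33
Choroid plexus,REF,0.2,-0.7,1.1,0.25
Frontal cerebral cortex,IIH,0.5,0.1,0.9,0.35
Frontal white matter,IIH,3.0,2.2,3.7,0.08
Temporal cerebral cortex,IIH,0.1,-0.4,0.6,0.37
Temporal white matter,IIH,3.0,2.2,3.7,0.14
Parietal cerebral cortex,IIH,1.8,1.2,2.4,0.26
Parietal white matter,IIH,5.8,5.6,5.9,0.06
Occipital cerebral cortex,IIH,1.4,0.3,2.4,0.26
Occipital white matter,IIH,3.0,1.3,4.6,0.06
Entorhinal cerebral cortex,IIH,-0.1,-0.8,0.6,0.69
Entorhinal white matter,IIH,2.4,1.7,3.2,0.45
Insular cerebral cortex,IIH,0.1,-0.7,0.8,0.67
Insular white matter,IIH,5.7,5.5,6.0,0.18
Cingulate cerebral cortex,IIH,0.3,-0.2,0.8,0.49
Cingulate white matter,IIH,3.0,1.7,4.2,0.08
Basal ganglia,IIH,2.9,0.8,4.9,0.03
Limbic structures,IIH,0.0,-0.5,0.5,0.40
Choroid plexus,IIH,-1.1,-3.3,1.1,0.25
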