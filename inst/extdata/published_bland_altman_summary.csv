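parameter,condition,n,bias,bias_ci_halfwidth,loa_upper,loa_lower
MeanIBI,Baseline,14,1.70,1.53,6.89,-3.49
MeanIBI,VideoClip,14,1.07,3.16,11.80,-9.66
MeanIBI,NRDriving,14,0.52,3.15,11.23,-10.19
RMSSD,Baseline,14,-1.07,4.19,13.14,-15.29
RMSSD,VideoClip,14,3.18,8.88,33.34,-26.97
RMSSD,NRDriving,14,8.19,6.92,31.67,-15.28
LFSpectrum,Baseline,14,5.42,5.03,22.49,-11.65
LFSpectrum,VideoClip,14,1.29,5.85,21.15,-18.58
LFSpectrum,NRDriving,14,-0.79,4.56,14.68,-16.25
MeanEDATonic,Baseline,14,0.15,0.70,2.54,-2.23
MeanEDATonic,VideoClip,14,-0.58,0.26,0.30,-1.46
MeanEDATonic,NRDriving,7,0.72,0.98,2.80,-1.35
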