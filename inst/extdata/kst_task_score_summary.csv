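task,outliers_removed,significant_change,confidence_interval,learning_effect,le_p_value,icc_consistency
BOB,0,1.33,0.94,-0.26,0.017,0.55
OH,0,1.65,1.17,-0.18,0.15,0.49
OHA,0,1.42,1.01,0.27,0.018,0.64
PM-D,1,1.82,1.28,-0.01,0.95,0.29
PM-ND,0,1.72,1.21,-0.01,0.94,0.36
RVGR-D,0,1.34,0.95,-0.78,1e-4,0.70
RVGR-ND,0,1.79,1.27,-0.67,1e-4,0.67
SPS,0,1.48,1.04,-0.39,0.0024,0.56
TMT,0,0.87,0.61,-0.23,0.0021,0.75
VGR-D,1,1.05,0.74,-0.07,0.44,0.30
VGR-ND,0,2.19,1.55,-0.17,0.31,0.33
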