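gene,p_child,p_adult,p_diff
C1orf106,0.57,0.51,0.52
C2orf74,0.58,0.73,
CCR4,0.58,0.79,0.72
CCR6,0.68,0.62,
CD28,,0.55,
FASLG,0.72,0.63,
ICOSLG,0.59,,0.57
IL18RAP,0.54,0.60,0.51
IL1RL1,,0.72,0.70
IL23A,0.70,0.69,
IL6,0.50,0.63,0.91
JAK2,0.65,0.65,
PLEK,0.52,0.61,0.51
STAT3,,0.56,
TAGAP,0.56,0.52,
TMEM187,,0.62,
TNFSF18,0.73,,0.54
UBE2L3,0.52,0.77,
VAMP3,,0.55,
ZFP36L1,,0.57,
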