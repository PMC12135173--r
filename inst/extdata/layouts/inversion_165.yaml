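# In(3LR)165 heterokaryotype: breakpoints in ve-h and th-cu, centromere in
# th-cu (the th-cu interval holds both the centromere and the right
# breakpoint, so it splits into three equal-share pieces).  Split fractions
# are fixed layout choices, not fitted.  Homokaryotype lengths in Morgans.
markers: [ve, h, th, cu, bx, e, ro, ca]
karyotype: hetero
lengths_homo_morgans: [0.276, 0.184, 0.045, 0.090, 0.158, 0.230, 0.114]
left_bp: {interval: 1, fraction: 0.5}
centromere: {interval: 3, fraction: 0.3333333333333333}
right_bp: {interval: 3, fraction: 0.6666666666666666}
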