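# In(3LR)190 heterokaryotype: breakpoints in h-th and cu-bx, centromere in
# th-cu.  Each split interval divides at its midpoint (fixed layout choice).
# Homokaryotype lengths in Morgans.
markers: [ve, h, th, cu, bx, e, ro, ca]
karyotype: hetero
lengths_homo_morgans: [0.276, 0.184, 0.045, 0.090, 0.158, 0.230, 0.114]
left_bp: {interval: 2, fraction: 0.5}
centromere: {interval: 3, fraction: 0.5}
right_bp: {interval: 4, fraction: 0.5}
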