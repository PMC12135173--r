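# Chromosome-3 marker map of the homokaryotype control cross
# (lengths are the fitted homokaryotype genetic map, in Morgans)
markers: [ve, h, th, cu, bx, e, ro, ca]
karyotype: homo
lengths_morgans: [0.276, 0.184, 0.045, 0.090, 0.158, 0.230, 0.114]
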