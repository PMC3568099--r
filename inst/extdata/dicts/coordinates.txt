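# anatomical coordinates and laterality terms (unigram)
central
left
right
bilateral
bilaterally
unilateral
unilaterally
proximal
proximally
distal
distally
anterior
posterior
superior
inferior
medial
medially
lateral
laterally
dorsal
ventral
upper
lower
axial
appendicular
peripheral
cranial
caudal
radial
ulnar
tibial
fibular
midline
symmetric
symmetrical
asymmetric
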