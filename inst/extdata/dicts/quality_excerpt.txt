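# small excerpt of quality unigrams, PATO-style
# (curated for this package; not a full ontology dump)
short
shortened
shortening
long
elongated
elongation
broad
broadened
broadening
wide
widened
widening
narrow
narrowed
narrowing
thin
thinned
thinning
thick
thickened
thickening
flat
flattened
flattening
square
squared
squaring
round
rounded
rounding
oval
ovoid
cupped
cupping
flared
flaring
bowed
bowing
curved
curving
angulated
angulation
irregular
irregularity
smooth
coarse
fine
dense
densification
sclerotic
sclerosis
lucent
lucency
osteopenic
osteopenia
hypoplastic
hypoplasia
aplastic
aplasia
dysplastic
dysplasia
hyperplastic
hyperplasia
absent
absence
missing
accessory
supernumerary
fused
fusion
unfused
fragmented
fragmentation
stippled
stippling
mottled
deformed
deformity
deformities
dislocated
dislocation
subluxed
subluxation
enlarged
enlargement
small
large
tiny
diminutive
gracile
slender
stubby
stocky
hypoplasic
overtubulated
undertubulated
undermodeled
undermodelling
overgrowth
undergrowth
delayed
advanced
premature
accelerated
decreased
increased
reduced
diminished
prominent
protruding
depressed
sunken
bell-shaped
cone-shaped
pear-shaped
wedge-shaped
spade-shaped
bullet-shaped
bone-in-bone
hitchhiker
trident
beaked
beaking
notched
notching
eroded
erosion
pitted
pitting
scalloped
scalloping
splayed
splaying
frayed
fraying
ragged
crenated
biconvex
biconcave
platyspondyly
brachydactyly
arachnodactyly
clinodactyly
camptodactyly
polydactyly
syndactyly
abnormal
abnormality
abnormalities
defect
defects
defective
malformed
malformation
hypomineralized
demineralized
osteolytic
osteosclerotic
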