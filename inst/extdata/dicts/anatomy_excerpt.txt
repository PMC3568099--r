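# small excerpt of skeletal anatomical-entity unigrams, FMA-style
# (curated for this package; not a full ontology dump)
skeleton
bone
bones
thorax
chest
rib
ribs
clavicle
clavicles
scapula
scapulae
sternum
spine
vertebra
vertebrae
atlas
axis
sacrum
coccyx
pelvis
ilium
ilia
ischium
pubis
acetabulum
acetabula
femur
femora
femurs
patella
patellae
tibia
tibiae
fibula
fibulae
humerus
humeri
radius
radii
ulna
ulnae
carpus
carpal
carpals
scaphoid
lunate
triquetrum
pisiform
trapezium
trapezoid
capitate
hamate
metacarpal
metacarpals
metatarsal
metatarsals
phalanx
phalanges
tarsal
tarsals
talus
calcaneus
navicular
cuboid
cuneiform
skull
cranium
calvaria
fontanelle
fontanelles
suture
sutures
mandible
maxilla
zygoma
orbit
orbits
clivus
sella
odontoid
epiphysis
epiphyses
metaphysis
metaphyses
diaphysis
diaphyses
physis
physes
cortex
cortices
medulla
trochanter
trochanters
condyle
condyles
epicondyle
malleolus
malleoli
tubercle
tuberosity
glenoid
symphysis
joint
joints
hip
hips
knee
knees
ankle
ankles
shoulder
shoulders
elbow
elbows
wrist
wrists
hand
hands
foot
feet
finger
fingers
thumb
thumbs
toe
toes
digit
digits
limb
limbs
arm
arms
forearm
forearms
leg
legs
thigh
thighs
head
heads
neck
necks
shaft
shafts
body
bodies
pedicle
pedicles
lamina
laminae
arch
arches
process
processes
ossicle
ossicles
sesamoid
sesamoids
trunk
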