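# synthetic general-English lexicon excerpt: word<TAB>lemma<TAB>coarse POS
# constructed for this package as a compact stand-in lexicon; coverage is
# intentionally partial, so out-of-lexicon tokens map to the "@" sentinel
the	the	det
a	a	det
an	an	det
and	and	conj
or	or	conj
but	but	conj
nor	nor	conj
of	of	prep
in	in	prep
on	on	prep
at	at	prep
to	to	prep
with	with	prep
without	without	prep
from	from	prep
by	by	prep
into	into	prep
between	between	prep
through	through	prep
during	during	prep
under	under	prep
over	over	prep
above	above	prep
below	below	prep
near	near	prep
is	be	verb
are	be	verb
was	be	verb
were	be	verb
be	be	verb
been	be	verb
being	be	verb
has	have	verb
have	have	verb
had	had	verb
shows	show	verb
show	show	verb
showing	show	verb
shown	show	verb
demonstrates	demonstrate	verb
demonstrate	demonstrate	verb
demonstrating	demonstrate	verb
reveals	reveal	verb
reveal	reveal	verb
revealing	reveal	verb
appears	appear	verb
appear	appear	verb
appearing	appear	verb
seen	see	verb
seems	seem	verb
noted	note	verb
note	note	verb
notes	note	verb
indicates	indicate	verb
indicate	indicate	verb
indicating	indicate	verb
affects	affect	verb
affect	affect	verb
affecting	affect	verb
involving	involve	verb
involves	involve	verb
obtained	obtain	verb
taken	take	verb
compared	compare	verb
this	this	det
that	that	det
these	these	det
those	those	det
there	there	adv
here	here	adv
also	also	adv
most	most	adv
more	more	adv
less	less	adv
very	very	adv
particularly	particularly	adv
especially	especially	adv
markedly	markedly	adv
mildly	mildly	adv
severely	severely	adv
slightly	slightly	adv
possibly	possibly	adv
probably	probably	adv
bilaterally	bilaterally	adv
not	not	adv
no	no	det
all	all	det
both	both	det
each	each	det
some	some	det
severe	severe	adj
mild	mild	adj
moderate	moderate	adj
subtle	subtle	adj
marked	marked	adj
normal	normal	adj
typical	typical	adj
classic	classic	adj
generalized	generalized	adj
diffuse	diffuse	adj
old	old	adj
new	new	adj
early	early	adj
late	late	adj
left	left	adj
right	right	adj
upper	upper	adj
lower	lower	adj
lateral	lateral	adj
central	central	adj
short	short	adj
long	long	adj
small	small	adj
large	large	adj
wide	wide	adj
narrow	narrow	adj
thin	thin	adj
thick	thick	adj
flat	flat	adj
figure	figure	noun
figures	figure	noun
image	image	noun
images	image	noun
radiograph	radiograph	noun
radiographs	radiograph	noun
view	view	noun
views	view	noun
film	film	noun
panel	panel	noun
panels	panel	noun
arrow	arrow	noun
arrows	arrow	noun
arrowhead	arrowhead	noun
patient	patient	noun
patients	patient	noun
case	case	noun
cases	case	noun
age	age	noun
ages	age	noun
year	year	noun
years	year	noun
month	month	noun
months	month	noun
birth	birth	noun
boy	boy	noun
girl	girl	noun
brother	brother	noun
sister	sister	noun
family	family	noun
examination	examination	noun
findings	finding	noun
finding	finding	noun
region	region	noun
regions	region	noun
area	area	noun
areas	area	noun
side	side	noun
sides	side	noun
bone	bone	noun
bones	bone	noun
hand	hand	noun
hands	hand	noun
foot	foot	noun
feet	foot	noun
head	head	noun
skull	skull	noun
spine	spine	noun
chest	chest	noun
ribs	rib	noun
rib	rib	noun
one	one	num
two	two	num
three	three	num
four	four	num
five	five	num
six	six	num
seven	seven	num
eight	eight	num
nine	nine	num
ten	ten	num
first	first	adj
second	second	adj
third	third	adj
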