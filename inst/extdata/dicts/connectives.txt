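# connective / prepositional tokens (unigram)
at
in
of
on
to
with
within
without
from
by
into
between
through
during
along
across
near
under
over
above
below
toward
towards
per
as
for
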