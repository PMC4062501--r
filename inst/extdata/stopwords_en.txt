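# English function-word stop list for tree-pruning rule 4.
# One word per line; lines starting with '#' are ignored.
# Deliberately absent: personal/relative pronouns (pronominal nodes routinely
# fill core roles: ARG1 "they", R-ARG0 "which") and every word that appears in
# the discourse/modal/negation word lists of the word-based candidate
# identifier (pruning them would contradict that identifier).
a
an
the
this
these
those
some
any
each
every
either
neither
both
all
much
many
few
more
most
other
another
such
no
nor
only
own
same
so
than
too
very
just
there
here
when
where
why
how
again
further
once
about
above
across
after
against
along
among
around
at
before
behind
below
beneath
beside
between
beyond
by
down
during
except
for
from
in
inside
into
near
of
off
on
onto
out
outside
over
past
since
through
throughout
till
to
toward
under
until
up
upon
with
within
without
and
but
or
yet
if
because
although
though
while
unless
whether
as
is
am
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
must
ought
per
via
versus
etc
e.g.
i.e.
meanwhile
otherwise
almost
quite
now
soon
often
always
well
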