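a
again
all
am
an
and
any
are
as
at
be
bit
but
by
can
could
did
do
does
down
for
from
get
going
got
had
has
have
he
her
here
his
how
i
if
im
in
into
is
it
its
just
like
little
me
my
need
no
not
now
of
on
one
or
our
out
over
she
so
some
that
the
their
them
then
there
they
this
to
trying
two
under
up
us
very
want
was
we
what
when
where
which
who
will
with
would
yes
you
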