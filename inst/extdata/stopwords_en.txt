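the
a
an
and
or
but
of
to
in
on
at
by
for
with
without
from
into
over
under
between
is
are
was
were
be
been
being
has
have
had
do
does
did
will
would
can
could
should
may
might
this
that
these
those
it
its
he
she
they
them
his
her
their
we
you
i
as
not
no
nor
so
than
then
there
here
when
where
which
who
whom
what
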