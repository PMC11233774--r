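# Synthetic stand-in, at reduced scale, for a corpus-derived list of the
# most common English word forms, ordered roughly from most to least common.
# One word per line; lines starting with '#' are ignored.
the
be
to
of
and
a
in
that
have
i
it
for
not
on
with
he
as
you
do
at
this
but
his
by
from
they
we
say
her
she
or
an
will
my
one
all
would
there
their
what
so
up
out
if
about
who
get
which
go
me
when
make
can
like
time
no
just
him
know
take
people
into
year
your
good
some
could
them
see
other
than
then
now
look
only
come
its
over
think
also
back
after
use
two
how
our
work
first
well
way
even
new
want
because
any
these
give
day
most
us
is
was
are
were
been
has
had
did
said
am
going
went
gone
got
made
came
looked
looking
wanted
right
okay
yes
no
please
thank
thanks
here
where
why
little
big
small
tall
happy
sad
red
blue
green
yellow
pink
black
white
brown
orange
purple
play
played
playing
read
reading
book
books
card
cards
picture
pictures
color
colors
draw
drawing
cut
paste
glue
paper
pencil
crayon
crayons
scissors
table
chair
floor
door
window
room
class
classroom
teacher
friend
friends
boy
girl
child
children
baby
mom
dad
family
home
house
school
toy
toys
block
blocks
ball
doll
truck
car
train
puzzle
game
games
story
stories
song
songs
sing
singing
dance
dancing
run
running
jump
jumping
walk
walking
sit
sitting
stand
standing
eat
eating
drink
drinking
lunch
snack
water
milk
juice
apple
banana
cookie
bread
hand
hands
finger
fingers
head
eyes
ears
nose
mouth
feet
dog
cat
bird
fish
bear
lion
duck
horse
cow
pig
sun
moon
star
stars
sky
rain
snow
tree
trees
flower
flowers
grass
today
tomorrow
yesterday
morning
afternoon
night
again
more
very
really
maybe
always
never
sometimes
together
turn
turns
share
sharing
help
helping
stop
start
finish
done
ready
wait
listen
hear
tell
told
ask
asked
answer
question
show
showed
find
found
put
putting
need
needed
let
try
tried
keep
hold
open
close
clean
wash
mirror
something
anything
everything
nothing
someone
everyone
one
two
three
four
five
six
seven
eight
nine
ten
first
second
last
next
before
after
under
over
behind
beside
between
inside
outside
top
bottom
left
right
front
around
away
down
off
near
far
fast
slow
hot
cold
warm
wet
dry
loud
quiet
soft
hard
nice
mean
fun
funny
silly
pretty
dirty
hungry
thirsty
tired
sleepy
sick
better
best
mine
yours
ours
his
hers
theirs
this
that
those
here
there
what
who
whose
when
where
why
how
yes
no
not
don't
can't
won't
didn't
isn't
doesn't
it's
let's
i'm
you're
we're
they're
he's
she's
i'll
we'll
gonna
wanna
oh
ah
hey
hi
hello
bye
goodbye
uh
um
wow
ouch
shh
okay
alright
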