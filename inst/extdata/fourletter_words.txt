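able
acid
aged
also
area
army
aunt
away
baby
back
bake
bald
ball
band
bang
bank
bare
bark
barn
base
bath
bead
beam
bean
bear
beat
bell
belt
bend
bent
best
bike
bill
bind
bird
bite
blew
blow
blue
boat
body
boil
bold
bolt
bomb
bond
bone
book
boom
bore
born
boss
both
bowl
buck
bulk
bull
bump
burn
bush
busy
cage
cake
calf
call
calm
came
camp
cane
cape
card
care
cart
case
cash
cast
cave
cell
chat
chef
chew
chin
chip
chop
cite
city
clan
claw
clay
clip
club
clue
coal
coat
code
coin
cold
colt
comb
come
cone
cook
cool
cope
copy
cord
core
cork
corn
cost
cove
crab
crew
crib
crop
cube
cuff
cult
curb
cure
curl
cute
damp
dare
dark
dart
dash
data
date
dawn
days
dead
deaf
deal
dear
debt
deck
deed
deem
deep
dent
deny
desk
dial
dice
diet
dime
dine
dirt
dish
disk
dive
dock
does
doll
dome
done
door
dorm
dose
dove
down
drag
draw
drew
drip
drop
drug
drum
dual
duck
dull
dumb
dump
dune
dusk
dust
duty
each
earn
ease
east
easy
edge
else
even
ever
evil
exit
face
fact
fade
fail
fair
fake
fall
fame
farm
fast
fate
fear
feed
feel
feet
fell
felt
file
fill
film
find
fine
fire
firm
fish
fist
five
flag
flat
flew
flip
flow
foam
fold
folk
food
foot
fork
form
fort
four
free
frog
from
fuel
full
fund
gain
game
gate
gave
gear
gene
gift
girl
give
glad
glow
glue
goal
goat
goes
gold
golf
gone
good
gown
grab
gray
grew
grey
grid
grim
grin
grip
grow
gulf
hair
half
hall
hand
hang
hard
harm
hate
have
hawk
head
heal
heap
hear
heat
heel
held
hell
help
herb
herd
here
hero
hide
high
hike
hill
hint
hire
hold
hole
holy
home
hood
hook
hope
horn
hose
host
hour
huge
hung
hunt
hurt
icon
idea
inch
into
iron
item
join
joke
jump
jury
just
keen
keep
kept
kick
kill
kind
king
kiss
kite
knee
knew
knit
knob
knot
know
lack
lady
laid
lake
lamb
lamp
land
lane
last
late
lawn
lazy
lead
leaf
lean
leap
left
lend
lens
less
life
lift
like
lime
limp
line
link
lion
list
live
load
loaf
loan
lock
logo
long
look
loop
lord
lose
loss
lost
loud
love
luck
lump
lung
made
mail
main
make
male
mall
many
mark
mask
mass
mast
meal
mean
meat
meet
melt
menu
mere
mild
mile
milk
mill
mind
mine
mint
miss
mist
mode
mood
moon
more
moss
most
moth
move
much
mule
must
nail
name
navy
near
neat
neck
need
nest
news
next
nice
nine
node
none
noon
norm
nose
note
noun
oats
obey
once
only
onto
open
oral
oven
over
pace
pack
page
paid
pain
pair
pale
palm
pant
park
part
pass
past
path
peak
pear
peel
peer
pile
pine
pink
pipe
plan
play
plot
plow
plug
plus
poem
poet
pole
poll
pond
pony
pool
poor
pork
port
pose
post
pour
pray
prey
pull
pump
pure
push
quit
quiz
race
rack
rage
rail
rain
rank
rare
rash
rate
read
real
reap
rear
rely
rent
rest
ribs
rice
rich
ride
ring
ripe
rise
risk
road
roam
roar
robe
rock
rode
role
roll
roof
room
root
rope
rose
ruin
rule
rush
rust
sack
safe
sage
said
sail
sake
sale
salt
same
sand
sane
save
scan
scar
seal
seam
seat
seed
seek
seem
seen
self
sell
send
sent
shed
ship
shop
shot
show
shut
sick
side
sigh
sign
silk
sing
sink
site
size
skin
skip
slab
slam
slap
sled
slid
slim
slip
slot
slow
snap
snow
soap
soar
sock
sofa
soft
soil
sold
sole
some
song
soon
sort
soul
soup
sour
spin
spot
star
stay
stem
step
stir
stop
such
suit
sung
sunk
sure
swam
swap
swim
tail
take
tale
talk
tall
tame
tank
tape
task
team
tear
tell
tend
tent
term
test
text
than
that
them
then
they
thin
this
thus
tide
tile
till
tilt
time
tiny
tire
toad
toll
tomb
tone
took
tool
torn
toss
tour
town
trap
tray
tree
trim
trip
true
tube
tune
turn
twig
twin
type
ugly
unit
upon
used
user
vain
vary
vast
veil
vein
verb
very
vest
view
vine
vote
wage
wait
wake
walk
wall
want
ward
warm
warn
wash
wasp
wave
ways
weak
wear
weed
week
weep
well
went
were
west
what
when
whip
whom
wide
wife
wild
will
wind
wine
wing
wipe
wire
wise
wish
with
wolf
wood
wool
word
wore
work
worm
worn
wrap
yard
yarn
yawn
yeah
year
yell
your
zero
zone
zoom
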