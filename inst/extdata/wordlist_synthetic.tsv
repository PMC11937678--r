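word	rank	length
a	1	1
I	2	1
of	3	2
to	4	2
in	5	2
it	6	2
is	7	2
be	8	2
as	9	2
at	10	2
so	11	2
we	12	2
he	13	2
by	14	2
or	15	2
on	16	2
do	17	2
if	18	2
me	19	2
my	20	2
up	21	2
an	22	2
go	23	2
no	24	2
us	25	2
am	26	2
the	27	3
and	28	3
for	29	3
are	30	3
but	31	3
not	32	3
you	33	3
all	34	3
any	35	3
can	36	3
had	37	3
her	38	3
was	39	3
one	40	3
our	41	3
out	42	3
day	43	3
get	44	3
has	45	3
him	46	3
his	47	3
how	48	3
man	49	3
new	50	3
now	51	3
old	52	3
see	53	3
two	54	3
way	55	3
who	56	3
boy	57	3
did	58	3
its	59	3
let	60	3
put	61	3
say	62	3
she	63	3
too	64	3
use	65	3
that	66	4
with	67	4
have	68	4
this	69	4
will	70	4
your	71	4
from	72	4
they	73	4
know	74	4
want	75	4
been	76	4
good	77	4
much	78	4
some	79	4
time	80	4
very	81	4
when	82	4
come	83	4
here	84	4
just	85	4
like	86	4
long	87	4
make	88	4
many	89	4
more	90	4
only	91	4
over	92	4
such	93	4
take	94	4
than	95	4
them	96	4
well	97	4
were	98	4
what	99	4
work	100	4
year	101	4
about	102	5
after	103	5
again	104	5
below	105	5
could	106	5
every	107	5
first	108	5
found	109	5
great	110	5
house	111	5
large	112	5
learn	113	5
never	114	5
other	115	5
place	116	5
plant	117	5
point	118	5
right	119	5
small	120	5
sound	121	5
spell	122	5
still	123	5
study	124	5
their	125	5
there	126	5
these	127	5
thing	128	5
think	129	5
three	130	5
water	131	5
where	132	5
which	133	5
world	134	5
would	135	5
write	136	5
around	137	6
before	138	6
better	139	6
between	140	7
change	141	6
develop	142	7
differ	143	6
follow	144	6
happen	145	6
letter	146	6
mother	147	6
number	148	6
people	149	6
picture	150	7
second	151	6
sentence	152	8
should	153	6
through	154	7
together	155	8
important	156	9
question	157	8
children	158	8
complete	159	8
different	160	9
communication	161	13
responsibility	162	14
understanding	163	13
characteristic	164	14
representative	165	14
recommendation	166	14
consideration	167	13
everything	168	10
understand	169	10
television	170	10
basketball	171	10
experience	172	10
information	173	11
temperature	174	11
interesting	175	11
performance	176	11
conversation	177	12
neighborhood	178	12
professional	179	12
organization	180	12
recommendations	181	15
representatives	182	15
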