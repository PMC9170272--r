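%
1	article
2	preposition
3	pronoun
4	auxverb
5	conjunction
6	adverb
7	negation
8	we
9	you
10	i
11	third_person
12	tentative
13	exclusive
14	posemo
15	negemo
16	motion
%
the	1
a	1
an	1
of	2
in	2
to	2
with	2
about	2
i	3	10
me	3	10
my	3	10
we	3	8
us	3	8
our	3	8
you	3	9
your	3	9
she	3	11
he	3	11
her	3	11
him	3	11
they	3	11
them	3	11
it	3
is	4
was	4
be	4
have	4
am	4
are	4
and	5
or	5
so	5
really	6
very	6
just	6
not	7
no	7
never	7
maybe	12
perhaps	12
tentativ*	12
guess	12
but	13
except	13
without	13
love	14
nice	14
sweet	14
good	14
happ*	14
hurt	15
ugly	15
nasty	15
sad	15
afraid	15
walk	16
move	16
go	16
went	16
run*	16
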