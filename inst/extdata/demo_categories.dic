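%
1	posemo
2	negemo
3	anxiety
4	anger
5	sad
6	social
7	family
8	religion
9	health
10	body
11	death
12	assent
13	swear
14	money
15	work
%
dodroar	1
godi	1
tree	1
taish	1
feedoaslan	1
doakroflaim	1
gait	1
librotres	1
tous	1
plain	1
skatround	1
krehodroar	1
krosoatar	1
kork	1
glees*	1
nelees	2
lainind	2
tofoum	2
guglon	2
sofis	2
ploush	2
krebibroas	2
plus	2
floun	2
leem	2
gleeglouslish	2
vibaimi	2
baikun	2
plutrou	2
drulm*	2
nou	3
troageflush	3
hobragol	3
braflind	3
brekailain	3
lakipork	3
fond	3
flohedrin	3
derk	3
gous	3
meeskagloal	3
brozoash	3
naiploa	3
dind	3
ris	4
dukround	4
glem	4
droat	4
hoash	4
troasloaglul	4
naroahis	4
noatand	4
vailuflur	4
drairadrai	4
troudrark	4
sum	4
pai	4
sas	4
drerk	5
broam	5
goakren	5
sketrous	5
plafloubend	5
lush	5
lepos	5
treemoafleesh	5
pluflesles	5
meegais	5
kragoas	5
drousaish	5
mehobir	5
zekrasler	5
zuziglir	6
glaroas	6
skeet	6
bil	6
laibidoun	6
veno	6
drukut	6
sal	6
plibark	6
dragluhee	6
taibu	6
futritrout	6
bair	6
vaibousin	6
slai	7
poaploal	7
musos	7
geer	7
zapeedot	7
skaivougil	7
foar	7
poun	7
posar	7
mar	7
buslurk	7
foaskoark	7
slatribees	7
glipuvand	7
drou	8
braifohand	8
moadrosh	8
diheekree	8
roabund	8
ploaskedees	8
zous	8
flol	8
slotazom	8
keesa	8
been	8
bes	8
pis	8
koum	8
zorel*	8
fliflees	9
pisketrun	9
koamiflet	9
tork	9
fal	9
baitrom	9
soakind	9
goaskebrosh	9
keem	9
skaish	9
meludrind	9
draru	9
gosaihel	9
hohugot	9
nel	10
mond	10
bafoam	10
kroazaitrum	10
floaseetrirk	10
globreeflosh	10
driploam	10
kadoul	10
slitu	10
saflu	10
fisoaskal	10
noavouslark	10
vourou	10
treer	10
slouslam	11
drasar	11
saind	11
flish	11
vasloufloam	11
flezeflairk	11
lesil	11
vurulu	11
brun	11
plaflit	11
plo	11
roukrour	11
gat	11
baplis	11
skaisloam	12
rin	12
boa	12
patrimou	12
broush	12
sleegloaglar	12
brit	12
nelund	12
saleesh	12
zoan	12
goarebair	12
netee	12
plumailat	12
masees	12
seragoun	13
poagal	13
dinilout	13
teepavi	13
fol	13
gais	13
gim	13
dreefofees	13
kreezeeru	13
bakish	13
bout	13
reslas	13
pelound	13
boar	13
flugurai	14
drukrenat	14
gloul	14
flotout	14
lohebet	14
sleekreesh	14
glouplit	14
rezuskoas	14
brark	14
droaheehark	14
touvaiboark	14
fladon	14
kaitouler	14
fiskobrourk	14
nezatraish	15
trailosark	15
flil	15
gleenaileesh	15
seebrobend	15
braboutend	15
foabreend	15
floash	15
kous	15
plevislee	15
taveelair	15
naiflon	15
reegiflark	15
pezouvai	15
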