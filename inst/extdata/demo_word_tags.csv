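word,tag
dodroar,posemo
godi,posemo
tree,posemo
taish,posemo
feedoaslan,posemo
doakroflaim,posemo
gait,posemo
librotres,posemo
tous,posemo
plain,posemo
skatround,posemo
krehodroar,posemo
krosoatar,posemo
kork,posemo
glees,posemo
gleesa,posemo
gleeso,posemo
nelees,negemo
lainind,negemo
tofoum,negemo
guglon,negemo
sofis,negemo
ploush,negemo
krebibroas,negemo
plus,negemo
floun,negemo
leem,negemo
gleeglouslish,negemo
vibaimi,negemo
baikun,negemo
plutrou,negemo
drulm,negemo
drulma,negemo
drulmi,negemo
nou,anxiety
troageflush,anxiety
hobragol,anxiety
braflind,anxiety
brekailain,anxiety
lakipork,anxiety
fond,anxiety
flohedrin,anxiety
derk,anxiety
gous,anxiety
meeskagloal,anxiety
brozoash,anxiety
naiploa,anxiety
dind,anxiety
ris,anger
dukround,anger
glem,anger
droat,anger
hoash,anger
troasloaglul,anger
naroahis,anger
noatand,anger
vailuflur,anger
drairadrai,anger
troudrark,anger
sum,anger
pai,anger
sas,anger
drerk,sad
broam,sad
goakren,sad
sketrous,sad
plafloubend,sad
lush,sad
lepos,sad
treemoafleesh,sad
pluflesles,sad
meegais,sad
kragoas,sad
drousaish,sad
mehobir,sad
zekrasler,sad
zuziglir,social
glaroas,social
skeet,social
bil,social
laibidoun,social
veno,social
drukut,social
sal,social
plibark,social
dragluhee,social
taibu,social
futritrout,social
bair,social
vaibousin,social
slai,family
poaploal,family
musos,family
geer,family
zapeedot,family
skaivougil,family
foar,family
poun,family
posar,family
mar,family
buslurk,family
foaskoark,family
slatribees,family
glipuvand,family
drou,religion
braifohand,religion
moadrosh,religion
diheekree,religion
roabund,religion
ploaskedees,religion
zous,religion
flol,religion
slotazom,religion
keesa,religion
been,religion
bes,religion
pis,religion
koum,religion
zorel,religion
zorela,religion
zorelum,religion
fliflees,health
pisketrun,health
koamiflet,health
tork,health
fal,health
baitrom,health
soakind,health
goaskebrosh,health
keem,health
skaish,health
meludrind,health
draru,health
gosaihel,health
hohugot,health
nel,body
mond,body
bafoam,body
kroazaitrum,body
floaseetrirk,body
globreeflosh,body
driploam,body
kadoul,body
slitu,body
saflu,body
fisoaskal,body
noavouslark,body
vourou,body
treer,body
slouslam,death
drasar,death
saind,death
flish,death
vasloufloam,death
flezeflairk,death
lesil,death
vurulu,death
brun,death
plaflit,death
plo,death
roukrour,death
gat,death
baplis,death
skaisloam,assent
rin,assent
boa,assent
patrimou,assent
broush,assent
sleegloaglar,assent
brit,assent
nelund,assent
saleesh,assent
zoan,assent
goarebair,assent
netee,assent
plumailat,assent
masees,assent
seragoun,swear
poagal,swear
dinilout,swear
teepavi,swear
fol,swear
gais,swear
gim,swear
dreefofees,swear
kreezeeru,swear
bakish,swear
bout,swear
reslas,swear
pelound,swear
boar,swear
flugurai,money
drukrenat,money
gloul,money
flotout,money
lohebet,money
sleekreesh,money
glouplit,money
rezuskoas,money
brark,money
droaheehark,money
touvaiboark,money
fladon,money
kaitouler,money
fiskobrourk,money
nezatraish,work
trailosark,work
flil,work
gleenaileesh,work
seebrobend,work
braboutend,work
foabreend,work
floash,work
kous,work
plevislee,work
taveelair,work
naiflon,work
reegiflark,work
pezouvai,work
lesorudrufeen,neutral
krohedoavoupurk,neutral
heel,neutral
drul,neutral
veekrinound,neutral
kran,neutral
kouloslepaikesh,neutral
droabretomoa,neutral
rir,neutral
maroasaish,neutral
fourogeeglend,neutral
broafoulou,neutral
dond,neutral
planouplamund,neutral
floupleede,neutral
bofouflaind,neutral
meritonout,neutral
flouskaitroabail,neutral
visan,neutral
boal,neutral
duvoul,neutral
faiteeta,neutral
rutraskeelemash,neutral
zurailahen,neutral
kifoun,neutral
soumomoules,neutral
pleefleedreezur,neutral
kosikeeraislom,neutral
trouhouhor,neutral
brapiround,neutral
zoafloaslekadraim,neutral
skoand,neutral
houkraigirikrin,neutral
droan,neutral
nefeslaibroadreel,neutral
zugla,neutral
deloulon,neutral
tivoar,neutral
zoadeer,neutral
gugoanoakrush,neutral
krizusaim,neutral
hahegor,neutral
zund,neutral
libodretreedut,neutral
zeesun,neutral
toutraidroun,neutral
dreegoaveskoutros,neutral
soutril,neutral
drinislem,neutral
kofa,neutral
verk,neutral
skoufoaboark,neutral
tetaikoul,neutral
dropen,neutral
kraimoaplom,neutral
fesleeglem,neutral
peedro,neutral
slaiflailebroskoal,neutral
trailibesluskeel,neutral
pladroahot,neutral
votreet,neutral
sloupand,neutral
slailund,neutral
vailork,neutral
fouskislosagoark,neutral
biruboubrakut,neutral
heet,neutral
druplokan,neutral
glouzeton,neutral
giplaimainu,neutral
droash,neutral
vaimunouplobrark,neutral
glos,neutral
koanibroagi,neutral
foazind,neutral
tobrouzoukeemom,neutral
nash,neutral
zomiflirk,neutral
nosand,neutral
toplopo,neutral
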