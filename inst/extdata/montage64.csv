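label,x,y,z
Fp1,-0.2864157153,0.9552286554,-0.0741906589
Fp2,0.2719951421,0.9593991053,-0.0746458269
F7,-0.7592504325,0.6374551056,-0.1311097601
F3,-0.5310113047,0.7307479352,0.4289923654
Fz,-0.0059193794,0.7561295716,0.6543951650
F4,0.5277426914,0.7417356541,0.4139032147
F8,0.7530583633,0.6440913564,-0.1343481526
FC5,-0.8761760511,0.4028786838,0.2645832452
FC1,-0.3615046403,0.4475329826,0.8179417000
FC2,0.3544979056,0.4574294955,0.8155301905
FC6,0.8724263065,0.4129018006,0.2615041929
T7,-0.9927591862,0.0146920997,-0.1192197149
C3,-0.7207029660,0.0614067466,0.6905189688
Cz,-0.0050610832,0.0813452852,0.9966731310
C4,0.7242775458,0.0697596409,0.6859705746
T8,0.9921601143,0.0266069768,-0.1221080524
TP9,-0.8439644019,-0.2851792182,-0.4543092580
CP5,-0.8867040321,-0.3224508120,0.3313328136
CP1,-0.3569844830,-0.2942074934,0.8865686830
CP2,0.3681958378,-0.2927181006,0.8824669618
CP6,0.8916490244,-0.3118389214,0.3282049731
TP10,0.8384834582,-0.2926625497,-0.4596674040
P7,-0.7933551916,-0.6076751819,-0.0363099617
P3,-0.5467583032,-0.6238070916,0.5584980487
Pz,-0.0055998879,-0.6154773564,0.7881346744
P4,0.5516012092,-0.6172902818,0.5609713130
P8,0.7905297456,-0.6112831647,-0.0373579158
PO9,-0.5331795699,-0.7715255431,-0.3470848349
O1,-0.3025795283,-0.9497999751,0.0795338689
Oz,-0.0080936138,-0.9901394903,0.1398509321
O2,0.2907969765,-0.9534599249,0.0796949818
PO10,0.5208532656,-0.7782978060,-0.3506628023
AF7,-0.5412146179,0.8334917018,-0.1112579005
AF3,-0.3382121600,0.9197983146,0.1989562649
AF4,0.3367760885,0.9192150420,0.2040234613
AF8,0.5301391253,0.8404304429,-0.1123796175
F5,-0.6969859592,0.6963633217,0.1711394078
F1,-0.2861597693,0.7476958922,0.5992190245
F2,0.2879994563,0.7538013855,0.5906266031
F6,0.6973367819,0.6983633356,0.1612763592
FT9,-0.8151911233,0.3054749871,-0.4920858307
FT7,-0.9247521418,0.3554739381,-0.1359108370
FC3,-0.6696962297,0.4384488981,0.5993909606
FC4,0.6678810548,0.4460740452,0.5957791897
FT8,0.9182356269,0.3710449671,-0.1384520347
FT10,0.8094261164,0.3078099717,-0.5000823767
C5,-0.9435196477,0.0408844490,0.3287843309
C1,-0.3837744043,0.0755228885,0.9203333635
C2,0.3859686850,0.0803454737,0.9190064086
C6,0.9445659756,0.0515054748,0.3242565401
TP7,-0.9445118309,-0.3166605538,-0.0873126282
CP3,-0.6708799579,-0.3094247336,0.6739261208
CPz,-0.0050438755,-0.2915409003,0.9565450657
CP4,0.6789107761,-0.3033581199,0.6686209758
TP8,0.9447159539,-0.3154996574,-0.0892845597
P5,-0.7231837081,-0.6259703714,0.2918328605
P1,-0.2890781298,-0.6192344182,0.7300565527
P2,0.2996854399,-0.6107838591,0.7328927033
P6,0.7195854680,-0.6298228198,0.2924379762
PO7,-0.5703997716,-0.8211316438,0.0196703840
PO3,-0.3798651611,-0.8484753761,0.3684996547
POz,-0.0070114283,-0.8628131790,0.5054742901
PO4,0.3674338805,-0.8559182877,0.3638629250
PO8,0.5630842743,-0.8261780380,0.0191298101
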