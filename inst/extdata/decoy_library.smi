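CC(=O)Nc1ccccc1 DEC001
CCC(=O)Nc1ccccc1 DEC002
CCCC(=O)Nc1ccccc1 DEC003
CC(C(=O)Nc1ccccc1)C DEC004
CN(CCC(=O)Nc1ccccc1)C DEC005
COCC(=O)Nc1ccccc1 DEC006
NC(=O)Nc1ccccc1 DEC007
COC(=O)Nc1ccccc1 DEC008
O=C(C(F)(F)F)Nc1ccccc1 DEC009
O=C(Nc1ccccc1)CN1CCCC1 DEC010
O=C(Nc1ccccc1)Cc1ccccc1 DEC011
CCOC(=O)Nc1ccccc1 DEC012
CN(C(=O)Nc1ccccc1)C DEC013
N#CC(=O)Nc1ccccc1 DEC014
FC(=O)Nc1ccccc1 DEC015
ClC(=O)Nc1ccccc1 DEC016
BrC(=O)Nc1ccccc1 DEC017
OCC(=O)Nc1ccccc1 DEC018
COCCC(=O)Nc1ccccc1 DEC019
O=C(c1ccncc1)Nc1ccccc1 DEC020
Cc1ccc(cc1)S(=O)(=O)N DEC021
CCc1ccc(cc1)S(=O)(=O)N DEC022
CCCc1ccc(cc1)S(=O)(=O)N DEC023
CC(c1ccc(cc1)S(=O)(=O)N)C DEC024
CN(CCc1ccc(cc1)S(=O)(=O)N)C DEC025
COCc1ccc(cc1)S(=O)(=O)N DEC026
Nc1ccc(cc1)S(=O)(=O)N DEC027
COc1ccc(cc1)S(=O)(=O)N DEC028
FC(c1ccc(cc1)S(=O)(=O)N)(F)F DEC029
NS(=O)(=O)c1ccc(cc1)CN1CCCC1 DEC030
NS(=O)(=O)c1ccc(cc1)Cc1ccccc1 DEC031
CCOc1ccc(cc1)S(=O)(=O)N DEC032
CN(c1ccc(cc1)S(=O)(=O)N)C DEC033
N#Cc1ccc(cc1)S(=O)(=O)N DEC034
Fc1ccc(cc1)S(=O)(=O)N DEC035
Clc1ccc(cc1)S(=O)(=O)N DEC036
Brc1ccc(cc1)S(=O)(=O)N DEC037
OCc1ccc(cc1)S(=O)(=O)N DEC038
COCCc1ccc(cc1)S(=O)(=O)N DEC039
NS(=O)(=O)c1ccc(cc1)c1ccncc1 DEC040
Cc1ccc2c(n1)cccc2 DEC041
CCc1ccc2c(n1)cccc2 DEC042
CCCc1ccc2c(n1)cccc2 DEC043
CC(c1ccc2c(n1)cccc2)C DEC044
CN(CCc1ccc2c(n1)cccc2)C DEC045
COCc1ccc2c(n1)cccc2 DEC046
Nc1ccc2c(n1)cccc2 DEC047
COc1ccc2c(n1)cccc2 DEC048
FC(c1ccc2c(n1)cccc2)(F)F DEC049
C1CCN(C1)Cc1ccc2c(n1)cccc2 DEC050
c1ccc(cc1)Cc1ccc2c(n1)cccc2 DEC051
CCOc1ccc2c(n1)cccc2 DEC052
CN(c1ccc2c(n1)cccc2)C DEC053
N#Cc1ccc2c(n1)cccc2 DEC054
Fc1ccc2c(n1)cccc2 DEC055
Clc1ccc2c(n1)cccc2 DEC056
Brc1ccc2c(n1)cccc2 DEC057
OCc1ccc2c(n1)cccc2 DEC058
COCCc1ccc2c(n1)cccc2 DEC059
n1ccc(cc1)c1ccc2c(n1)cccc2 DEC060
CN1CCN(CC1)C(=O)c1ccc(cc1)C DEC061
CCc1ccc(cc1)C(=O)N1CCN(CC1)C DEC062
CCCc1ccc(cc1)C(=O)N1CCN(CC1)C DEC063
CN1CCN(CC1)C(=O)c1ccc(cc1)C(C)C DEC064
CN(CCc1ccc(cc1)C(=O)N1CCN(CC1)C)C DEC065
COCc1ccc(cc1)C(=O)N1CCN(CC1)C DEC066
CN1CCN(CC1)C(=O)c1ccc(cc1)N DEC067
COc1ccc(cc1)C(=O)N1CCN(CC1)C DEC068
CN1CCN(CC1)C(=O)c1ccc(cc1)C(F)(F)F DEC069
CN1CCN(CC1)C(=O)c1ccc(cc1)CN1CCCC1 DEC070
CN1CCN(CC1)C(=O)c1ccc(cc1)Cc1ccccc1 DEC071
CCOc1ccc(cc1)C(=O)N1CCN(CC1)C DEC072
CN1CCN(CC1)C(=O)c1ccc(cc1)N(C)C DEC073
CN1CCN(CC1)C(=O)c1ccc(cc1)C#N DEC074
CN1CCN(CC1)C(=O)c1ccc(cc1)F DEC075
CN1CCN(CC1)C(=O)c1ccc(cc1)Cl DEC076
CN1CCN(CC1)C(=O)c1ccc(cc1)Br DEC077
OCc1ccc(cc1)C(=O)N1CCN(CC1)C DEC078
COCCc1ccc(cc1)C(=O)N1CCN(CC1)C DEC079
CN1CCN(CC1)C(=O)c1ccc(cc1)c1ccncc1 DEC080
Cc1nnc(o1)c1ccccc1 DEC081
CCc1nnc(o1)c1ccccc1 DEC082
CCCc1nnc(o1)c1ccccc1 DEC083
CC(c1nnc(o1)c1ccccc1)C DEC084
CN(CCc1nnc(o1)c1ccccc1)C DEC085
COCc1nnc(o1)c1ccccc1 DEC086
Nc1nnc(o1)c1ccccc1 DEC087
COc1nnc(o1)c1ccccc1 DEC088
FC(c1nnc(o1)c1ccccc1)(F)F DEC089
c1ccc(cc1)c1nnc(o1)CN1CCCC1 DEC090
c1ccc(cc1)Cc1nnc(o1)c1ccccc1 DEC091
CCOc1nnc(o1)c1ccccc1 DEC092
CN(c1nnc(o1)c1ccccc1)C DEC093
N#Cc1nnc(o1)c1ccccc1 DEC094
Fc1nnc(o1)c1ccccc1 DEC095
Clc1nnc(o1)c1ccccc1 DEC096
Brc1nnc(o1)c1ccccc1 DEC097
OCc1nnc(o1)c1ccccc1 DEC098
COCCc1nnc(o1)c1ccccc1 DEC099
c1ccc(cc1)c1nnc(o1)c1ccncc1 DEC100
CC(=O)Nc1ccc(cc1)C DEC101
CCc1ccc(cc1)NC(=O)C DEC102
CCCc1ccc(cc1)NC(=O)C DEC103
CC(=O)Nc1ccc(cc1)C(C)C DEC104
CN(CCc1ccc(cc1)NC(=O)C)C DEC105
COCc1ccc(cc1)NC(=O)C DEC106
CC(=O)Nc1ccc(cc1)N DEC107
COc1ccc(cc1)NC(=O)C DEC108
CC(=O)Nc1ccc(cc1)C(F)(F)F DEC109
CC(=O)Nc1ccc(cc1)CN1CCCC1 DEC110
CC(=O)Nc1ccc(cc1)Cc1ccccc1 DEC111
CCOc1ccc(cc1)NC(=O)C DEC112
CC(=O)Nc1ccc(cc1)N(C)C DEC113
N#Cc1ccc(cc1)NC(=O)C DEC114
CC(=O)Nc1ccc(cc1)F DEC115
CC(=O)Nc1ccc(cc1)Cl DEC116
CC(=O)Nc1ccc(cc1)Br DEC117
OCc1ccc(cc1)NC(=O)C DEC118
COCCc1ccc(cc1)NC(=O)C DEC119
CC(=O)Nc1ccc(cc1)c1ccncc1 DEC120
OC(=O)c1ccc(cc1)C DEC121
CCc1ccc(cc1)C(=O)O DEC122
CCCc1ccc(cc1)C(=O)O DEC123
CC(c1ccc(cc1)C(=O)O)C DEC124
CN(CCc1ccc(cc1)C(=O)O)C DEC125
COCc1ccc(cc1)C(=O)O DEC126
OC(=O)c1ccc(cc1)N DEC127
COc1ccc(cc1)C(=O)O DEC128
OC(=O)c1ccc(cc1)C(F)(F)F DEC129
OC(=O)c1ccc(cc1)CN1CCCC1 DEC130
OC(=O)c1ccc(cc1)Cc1ccccc1 DEC131
CCOc1ccc(cc1)C(=O)O DEC132
CN(c1ccc(cc1)C(=O)O)C DEC133
N#Cc1ccc(cc1)C(=O)O DEC134
OC(=O)c1ccc(cc1)F DEC135
OC(=O)c1ccc(cc1)Cl DEC136
OC(=O)c1ccc(cc1)Br DEC137
OCc1ccc(cc1)C(=O)O DEC138
COCCc1ccc(cc1)C(=O)O DEC139
OC(=O)c1ccc(cc1)c1ccncc1 DEC140
Cc1nc2c([nH]1)cccc2 DEC141
CCc1nc2c([nH]1)cccc2 DEC142
CCCc1nc2c([nH]1)cccc2 DEC143
CC(c1nc2c([nH]1)cccc2)C DEC144
CN(CCc1nc2c([nH]1)cccc2)C DEC145
COCc1nc2c([nH]1)cccc2 DEC146
Nc1nc2c([nH]1)cccc2 DEC147
COc1nc2c([nH]1)cccc2 DEC148
FC(c1nc2c([nH]1)cccc2)(F)F DEC149
C1CCN(C1)Cc1nc2c([nH]1)cccc2 DEC150
c1ccc(cc1)Cc1nc2c([nH]1)cccc2 DEC151
CCOc1nc2c([nH]1)cccc2 DEC152
CN(c1nc2c([nH]1)cccc2)C DEC153
N#Cc1nc2c([nH]1)cccc2 DEC154
Fc1nc2c([nH]1)cccc2 DEC155
Clc1nc2c([nH]1)cccc2 DEC156
Brc1nc2c([nH]1)cccc2 DEC157
OCc1nc2c([nH]1)cccc2 DEC158
COCCc1nc2c([nH]1)cccc2 DEC159
n1ccc(cc1)c1nc2c([nH]1)cccc2 DEC160
O=C(C(C)C)Nc1ccccn1 DEC161
CCC(C(=O)Nc1ccccn1)C DEC162
CCCC(C(=O)Nc1ccccn1)C DEC163
CC(C(C(=O)Nc1ccccn1)C)C DEC164
CN(CCC(C(=O)Nc1ccccn1)C)C DEC165
COCC(C(=O)Nc1ccccn1)C DEC166
O=C(C(N)C)Nc1ccccn1 DEC167
COC(C(=O)Nc1ccccn1)C DEC168
O=C(C(C(F)(F)F)C)Nc1ccccn1 DEC169
O=C(C(CN1CCCC1)C)Nc1ccccn1 DEC170
O=C(C(Cc1ccccc1)C)Nc1ccccn1 DEC171
CCOC(C(=O)Nc1ccccn1)C DEC172
CN(C(C(=O)Nc1ccccn1)C)C DEC173
N#CC(C(=O)Nc1ccccn1)C DEC174
O=C(C(F)C)Nc1ccccn1 DEC175
O=C(C(Cl)C)Nc1ccccn1 DEC176
O=C(C(Br)C)Nc1ccccn1 DEC177
OCC(C(=O)Nc1ccccn1)C DEC178
COCCC(C(=O)Nc1ccccn1)C DEC179
CC(C(=O)Nc1ccccn1)c1ccncc1 DEC180
CN(CCOc1ccc(cc1)C)C DEC181
CCc1ccc(cc1)OCCN(C)C DEC182
CCCc1ccc(cc1)OCCN(C)C DEC183
CN(CCOc1ccc(cc1)C(C)C)C DEC184
CN(CCOc1ccc(cc1)CCN(C)C)C DEC185
COCc1ccc(cc1)OCCN(C)C DEC186
CN(CCOc1ccc(cc1)N)C DEC187
COc1ccc(cc1)OCCN(C)C DEC188
CN(CCOc1ccc(cc1)C(F)(F)F)C DEC189
CN(CCOc1ccc(cc1)CN1CCCC1)C DEC190
CN(CCOc1ccc(cc1)Cc1ccccc1)C DEC191
CCOc1ccc(cc1)OCCN(C)C DEC192
CN(CCOc1ccc(cc1)N(C)C)C DEC193
CN(CCOc1ccc(cc1)C#N)C DEC194
CN(CCOc1ccc(cc1)F)C DEC195
CN(CCOc1ccc(cc1)Cl)C DEC196
CN(CCOc1ccc(cc1)Br)C DEC197
OCc1ccc(cc1)OCCN(C)C DEC198
COCCc1ccc(cc1)OCCN(C)C DEC199
CN(CCOc1ccc(cc1)c1ccncc1)C DEC200
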