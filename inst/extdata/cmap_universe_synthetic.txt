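APOB
APOF
ASGR2
C9
CPB2
CPN2
CRP
CYP2E1
DPYS
FGA
FGB
FGG
FGL1
GC
HPR
ITIH3
ITIH4
LBP
ORM1
PRG4
VTN
SYNBG0001
SYNBG0002
SYNBG0003
SYNBG0004
SYNBG0005
SYNBG0006
SYNBG0007
SYNBG0008
SYNBG0009
SYNBG0010
SYNBG0011
SYNBG0012
SYNBG0013
SYNBG0014
SYNBG0015
SYNBG0016
SYNBG0017
SYNBG0018
SYNBG0019
SYNBG0020
SYNBG0021
SYNBG0022
SYNBG0023
SYNBG0024
SYNBG0025
SYNBG0026
SYNBG0027
SYNBG0028
SYNBG0029
SYNBG0030
SYNBG0031
SYNBG0032
SYNBG0033
SYNBG0034
SYNBG0035
SYNBG0036
SYNBG0037
SYNBG0038
SYNBG0039
SYNBG0040
SYNBG0041
SYNBG0042
SYNBG0043
SYNBG0044
SYNBG0045
SYNBG0046
SYNBG0047
SYNBG0048
SYNBG0049
SYNBG0050
SYNBG0051
SYNBG0052
SYNBG0053
SYNBG0054
SYNBG0055
SYNBG0056
SYNBG0057
SYNBG0058
SYNBG0059
SYNBG0060
SYNBG0061
SYNBG0062
SYNBG0063
SYNBG0064
SYNBG0065
SYNBG0066
SYNBG0067
SYNBG0068
SYNBG0069
SYNBG0070
SYNBG0071
SYNBG0072
SYNBG0073
SYNBG0074
SYNBG0075
SYNBG0076
SYNBG0077
SYNBG0078
SYNBG0079
SYNBG0080
SYNBG0081
SYNBG0082
SYNBG0083
SYNBG0084
SYNBG0085
SYNBG0086
SYNBG0087
SYNBG0088
SYNBG0089
SYNBG0090
SYNBG0091
SYNBG0092
SYNBG0093
SYNBG0094
SYNBG0095
SYNBG0096
SYNBG0097
SYNBG0098
SYNBG0099
SYNBG0100
SYNBG0101
SYNBG0102
SYNBG0103
SYNBG0104
SYNBG0105
SYNBG0106
SYNBG0107
SYNBG0108
SYNBG0109
SYNBG0110
SYNBG0111
SYNBG0112
SYNBG0113
SYNBG0114
SYNBG0115
SYNBG0116
SYNBG0117
SYNBG0118
SYNBG0119
SYNBG0120
SYNBG0121
SYNBG0122
SYNBG0123
SYNBG0124
SYNBG0125
SYNBG0126
SYNBG0127
SYNBG0128
SYNBG0129
SYNBG0130
SYNBG0131
SYNBG0132
SYNBG0133
SYNBG0134
SYNBG0135
SYNBG0136
SYNBG0137
SYNBG0138
SYNBG0139
SYNBG0140
SYNBG0141
SYNBG0142
SYNBG0143
SYNBG0144
SYNBG0145
SYNBG0146
SYNBG0147
SYNBG0148
SYNBG0149
SYNBG0150
SYNBG0151
SYNBG0152
SYNBG0153
SYNBG0154
SYNBG0155
SYNBG0156
SYNBG0157
SYNBG0158
SYNBG0159
SYNBG0160
SYNBG0161
SYNBG0162
SYNBG0163
SYNBG0164
SYNBG0165
SYNBG0166
SYNBG0167
SYNBG0168
SYNBG0169
SYNBG0170
SYNBG0171
SYNBG0172
SYNBG0173
SYNBG0174
SYNBG0175
SYNBG0176
SYNBG0177
SYNBG0178
SYNBG0179
SYNBG0180
SYNBG0181
SYNBG0182
SYNBG0183
SYNBG0184
SYNBG0185
SYNBG0186
SYNBG0187
SYNBG0188
SYNBG0189
SYNBG0190
SYNBG0191
SYNBG0192
SYNBG0193
SYNBG0194
SYNBG0195
SYNBG0196
SYNBG0197
SYNBG0198
SYNBG0199
SYNBG0200
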