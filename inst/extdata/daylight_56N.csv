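month_day,dawn_min,dusk_min
09-01,217,1223
09-02,220,1220
09-03,223,1217
09-04,226,1214
09-05,229,1211
09-06,232,1208
09-07,234,1206
09-08,237,1203
09-09,240,1200
09-10,243,1197
09-11,246,1194
09-12,248,1192
09-13,251,1189
09-14,254,1186
09-15,256,1184
09-16,259,1181
09-17,262,1178
09-18,265,1175
09-19,267,1173
09-20,270,1170
09-21,272,1168
09-22,275,1165
09-23,278,1162
09-24,280,1160
09-25,283,1157
09-26,285,1155
09-27,288,1152
09-28,290,1150
09-29,293,1147
09-30,295,1145
10-01,298,1142
10-02,300,1140
10-03,302,1138
10-04,305,1135
10-05,307,1133
10-06,309,1131
10-07,312,1128
10-08,314,1126
10-09,316,1124
10-10,319,1121
10-11,321,1119
10-12,323,1117
10-13,326,1114
10-14,328,1112
10-15,330,1110
10-16,332,1108
10-17,334,1106
10-18,336,1104
10-19,339,1101
10-20,341,1099
10-21,343,1097
10-22,345,1095
10-23,347,1093
10-24,349,1091
10-25,351,1089
10-26,353,1087
10-27,355,1085
10-28,357,1083
10-29,359,1081
10-30,361,1079
10-31,362,1078
11-01,364,1076
11-02,366,1074
11-03,368,1072
11-04,370,1070
11-05,372,1068
11-06,373,1067
11-07,375,1065
11-08,377,1063
11-09,378,1062
11-10,380,1060
11-11,381,1059
11-12,383,1057
11-13,385,1055
11-14,386,1054
11-15,388,1052
11-16,389,1051
11-17,390,1050
11-18,392,1048
11-19,393,1047
11-20,394,1046
11-21,396,1044
11-22,397,1043
11-23,398,1042
11-24,399,1041
11-25,400,1040
11-26,402,1038
11-27,403,1037
11-28,404,1036
11-29,405,1035
11-30,406,1034
12-01,406,1034
12-02,407,1033
12-03,408,1032
12-04,409,1031
12-05,410,1030
12-06,410,1030
12-07,411,1029
12-08,412,1028
12-09,412,1028
12-10,413,1027
12-11,413,1027
12-12,414,1026
12-13,414,1026
12-14,414,1026
12-15,415,1025
12-16,415,1025
12-17,415,1025
12-18,415,1025
12-19,416,1024
12-20,416,1024
12-21,416,1024
12-22,416,1024
12-23,416,1024
12-24,415,1025
12-25,415,1025
12-26,415,1025
12-27,415,1025
12-28,415,1025
12-29,414,1026
12-30,414,1026
12-31,413,1027
01-01,413,1027
01-02,412,1028
01-03,412,1028
01-04,411,1029
01-05,411,1029
01-06,410,1030
01-07,409,1031
01-08,408,1032
01-09,408,1032
01-10,407,1033
01-11,406,1034
01-12,405,1035
01-13,404,1036
01-14,403,1037
01-15,402,1038
01-16,401,1039
01-17,400,1040
01-18,398,1042
01-19,397,1043
01-20,396,1044
01-21,395,1045
01-22,393,1047
01-23,392,1048
01-24,391,1049
01-25,389,1051
01-26,388,1052
01-27,386,1054
01-28,385,1055
01-29,383,1057
01-30,382,1058
01-31,380,1060
02-01,379,1061
02-02,377,1063
02-03,375,1065
02-04,374,1066
02-05,372,1068
02-06,370,1070
02-07,368,1072
02-08,367,1073
02-09,365,1075
02-10,363,1077
02-11,361,1079
02-12,359,1081
02-13,357,1083
02-14,355,1085
02-15,353,1087
02-16,351,1089
02-17,349,1091
02-18,347,1093
02-19,345,1095
02-20,343,1097
02-21,341,1099
02-22,339,1101
02-23,337,1103
02-24,335,1105
02-25,333,1107
02-26,330,1110
02-27,328,1112
02-28,326,1114
03-01,324,1116
03-02,322,1118
03-03,319,1121
03-04,317,1123
03-05,315,1125
03-06,312,1128
03-07,310,1130
03-08,308,1132
03-09,305,1135
03-10,303,1137
03-11,301,1139
03-12,298,1142
03-13,296,1144
03-14,293,1147
03-15,291,1149
03-16,288,1152
03-17,286,1154
03-18,283,1157
03-19,281,1159
03-20,278,1162
03-21,276,1164
03-22,273,1167
03-23,270,1170
03-24,268,1172
03-25,265,1175
03-26,263,1177
03-27,260,1180
03-28,257,1183
03-29,254,1186
03-30,252,1188
03-31,249,1191
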