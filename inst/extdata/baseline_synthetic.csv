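stratum,age_start,age_end,hazard
0,40,45,5.10474340041544e-06
0,45,50,1.1943296826672e-05
0,50,55,2.79430968221407e-05
0,55,60,6.53769785129847e-05
0,60,65,0.000152959041966338
0,65,70,0.000357870141010158
0,70,75,0.000837289748812727
0,75,80,0.0019589623249596
0,80,85,0.00458328003663335
1,40,45,1.53142302012463e-05
1,45,50,3.58298904800159e-05
1,50,55,8.38292904664222e-05
1,55,60,0.000196130935538954
1,60,65,0.000458877125899014
1,65,70,0.00107361042303047
1,70,75,0.00251186924643818
1,75,80,0.0058768869748788
1,80,85,0.0137498401099
2,40,45,4.08379472033235e-05
2,45,50,9.55463746133757e-05
2,50,55,0.000223544774577126
2,55,60,0.000523015828103878
2,60,65,0.0012236723357307
2,65,70,0.00286296112808126
2,70,75,0.00669831799050181
2,75,80,0.0156716985996768
2,80,85,0.0366662402930668
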