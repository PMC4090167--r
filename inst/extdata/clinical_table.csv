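ID,Age,Grade,TNM,Subtype,Familial,ER,PR,Her-2
NF-BC 1,33,GN3/GH3,IIA,Luminal B,(-),POS,POS,POS
NF-BC 2,35,GN3/GH2,IIA,Luminal B,(-),POS,POS,POS
NF-BC 3,33,GN3/GH3,IIB,Luminal A,(-),POS,POS,NEG
NF-BC 4,25,GN2/GH2,IV,Trip. NEG,(-),NEG,NEG,NEG
NF-BC 5,33,GH2/GN3,IIB,Luminal A,(-),POS,NEG,NEG
NF-BC 6,30,GN2/GH2,IIB,Luminal B,(-),POS,POS,POS
NF-BC 7,26,GN3/GH3,IIB,Trip. NEG,(-),NEG,NEG,NEG
NF-BC 8,29,GN3/GH3,IIA,Luminal A,(-),POS,NEG,NEG
NF-BC 9,33,GN2/GH2,IIIA,Luminal A,(-),POS,NEG,NEG
NF-BC 10,35,GN3/GH3,IIA,Trip. NEG,(-),NEG,NEG,NEG
NF-BC 11,34,GN2/GH1,IIA,Luminal B,(-),POS,NEG,POS
NF-BC 12,36,GN3/GH3,IIA,Luminal B,(-),POS,POS,POS
NF-BC 13,35,GN3/GH2,IIB,Luminal A,(-),POS,POS,NEG
NF-BC 14,32,GH2,IIA,Luminal A,(-),POS,POS,NEG
NF-BC 15,34,GN3/GH2,IIB,Trip. NEG,(-),NEG,NEG,NEG
NF-BC 16,30,GH2,IIIB,Luminal A,(-),POS,POS,NEG
NF-BC 17,29,GH2,IIA,Luminal B,(-),POS,POS,POS
NF-BC 18,31,GH2,IIIA,Luminal A,(-),POS,POS,NEG
NF-BC 19,33,GN2/GH1,IIA,Luminal A,(-),POS,POS,NEG
NF-BC 20,35,GH2,IIIB,Luminal A,(-),POS,POS,NEG
NF-BC 21,28,GN2/GH2,IIA,Luminal A,(-),POS,POS,NEG
NF-BC 22,33,GH2/GN2,IIB,Luminal A,(-),POS,NEG,NEG
NF-BC 23,33,NA,IIA,Luminal A,(-),POS,NEG,NEG
NF-BC 24,26,GN3/GH2,IIIA,Luminal B,(-),POS,POS,POS
NF-BC 25,22,GN3 GH2,IIA,Her-2,(-),NEG,NEG,POS
NF-BC 26,34,GH2,IIIA,Luminal A,(-),POS,POS,NEG
F-BC 1,28,GN3/GH2,IIB,Luminal B,(+),POS,POS,POS
F-BC 2,34,GN3/GH2,IIB,Luminal A,(+),POS,POS,NEG
F-BC 3,35,GN3/GH2,IIA,Luminal A,(+),POS,POS,NEG
F-BC 4,29,GN3/GH3,IIIA,Luminal A,(+),POS,POS,NEG
F-BC 5,29,GN3/GH3,IIA,Trip. NEG,(+),NEG,NEG,NEG
F-BC 6,29,GN3/GH3,IIB,Luminal A,(+),POS,POS,NEG
F-BC 7,34,GN3/GH2,IIB,Luminal A,(+),POS,POS,NEG
F-BC 8,33,NA,I,Luminal A,(+),POS,NEG,NEG
F-BC 9,29,NA,I,Luminal A,(+),POS,POS,NEG
F-BC 10,28,GN3/GH3,IIIB,TripNeg,(+),NEG,NEG,NEG
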