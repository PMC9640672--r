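"site_id","species","count"
"site_0001","Species 0005",2
"site_0001","Species 0011",1
"site_0001","Species 0013",2
"site_0002","Species 0003",1
"site_0002","Species 0005",3
"site_0002","Species 0013",1
"site_0002","Species 0014",1
"site_0003","Species 0009",6
"site_0003","Species 0011",2
"site_0004","Species 0002",3
"site_0004","Species 0005",10
"site_0004","Species 0006",8
"site_0004","Species 0013",2
"site_0004","Species 0014",12
"site_0005","Species 0002",1
"site_0005","Species 0005",2
"site_0005","Species 0010",3
"site_0005","Species 0013",1
"site_0005","Species 0015",3
"site_0006","Species 0002",3
"site_0006","Species 0005",2
"site_0006","Species 0008",6
"site_0006","Species 0013",3
"site_0006","Species 0014",1
"site_0007","Species 0007",10
"site_0007","Species 0008",3
"site_0007","Species 0012",1
"site_0007","Species 0013",3
"site_0008","Species 0005",4
"site_0008","Species 0006",2
"site_0008","Species 0008",4
"site_0008","Species 0013",2
"site_0009","Species 0002",1
"site_0009","Species 0005",2
"site_0009","Species 0007",2
"site_0009","Species 0013",3
"site_0010","Species 0006",4
"site_0010","Species 0013",2
"site_0011","Species 0001",3
"site_0011","Species 0004",2
"site_0011","Species 0009",1
"site_0011","Species 0010",1
"site_0011","Species 0011",2
"site_0011","Species 0013",2
"site_0011","Species 0014",4
"site_0012","Species 0004",2
"site_0012","Species 0005",1
"site_0012","Species 0013",3
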