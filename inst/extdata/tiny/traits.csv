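"species","nesting","sociality","diet","size","itd_mm","parasitic"
"Species 0001","below","solitary","generalist","no_information",NA,FALSE
"Species 0002","below","solitary","generalist","small",0.98,FALSE
"Species 0003","below","solitary","generalist","large",5.92,TRUE
"Species 0004","below","solitary","generalist","no_information",NA,FALSE
"Species 0005","below","solitary","specialist","small",1.46,TRUE
"Species 0006","above","solitary","specialist","small",1.85,FALSE
"Species 0007","above","solitary","specialist","large",2.65,FALSE
"Species 0008","below","social","generalist","small",1.74,FALSE
"Species 0009","above","solitary","generalist","small",1.65,FALSE
"Species 0010","above","social","generalist","small",1.52,FALSE
"Species 0011","below","solitary","generalist","large",5.24,FALSE
"Species 0012","below","solitary","specialist","small",1.05,FALSE
"Species 0013","no_information","solitary","generalist","small",1,TRUE
"Species 0014","below","solitary","generalist","small",1.55,FALSE
"Species 0015","above","solitary","generalist","small",1.79,FALSE
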