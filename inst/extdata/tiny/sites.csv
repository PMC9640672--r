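"site_id","x","y","pop_density","impervious_pct","region","active_days","passive_hours","kick_net"
"site_0001",11455.5902429856,31432.1599900723,106.330239352299,4.62047670775578,"Continental",5,123.2,0
"site_0002",21569.3993377499,45374.5656996034,1069.64453693866,25.6841671395424,"Continental",3,149,0
"site_0003",29341.1948718131,7987.1776048094,974.313451041598,26.2453101920337,"Mediterranean",2,304.7,0
"site_0004",32163.5031839833,14474.2677104659,8592.27122167934,76.0438667149765,"Mediterranean",10,137.5,0
"site_0005",5103.99648919702,33730.7097273879,1029.18899212107,23.7792979668102,"Continental",1,421.6,0
"site_0006",6936.2556328997,32858.4213741124,92.3150488335403,1.21167427184663,"Continental",11,0,0
"site_0007",29145.1619938016,7464.42461386323,882.656044517624,13.7627047368074,"Mediterranean",0,485.1,0
"site_0008",32728.5810839385,103.059178218246,2027.41520231806,95.744634962,"Mediterranean",17,0,0
"site_0009",38639.4481756724,38311.2476440147,183.825119609805,13.2699231982408,"Continental",2,11.3,1
"site_0010",47074.1912140511,8709.6206494607,571.978801546181,77.7478618867096,"Alpine",13,0,0
"site_0011",7949.25263617188,15679.1948829778,1718.48075601095,91.3182310980699,"Atlantic",2,156.1,0
"site_0012",13903.3653889783,5307.09899030626,166.702001831082,33.8174376683119,"Atlantic",1,552.4,0
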