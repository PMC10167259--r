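site_label,charge,d0,r0
C1,1.2369,0.070,3.50
O1,-0.55,0.120,2.80
O2,-0.50,0.120,2.80
OA,-0.6269,0.152,2.80
HA,0.44,0.046,0.90
N,1.00,0.170,4.00
O,-0.40,0.152,2.80
HO,0.40,0.046,0.90
Cl,-1.00,0.150,3.00
OW,-0.834,0.152,3.10
HW1,0.417,0.046,0.80
HW2,0.417,0.046,0.80
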