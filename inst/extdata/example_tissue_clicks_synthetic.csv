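"subject_id","medium","click_index","time_s"
"EXAMPLE01","tissue",1,0.0728862515685679
"EXAMPLE01","tissue",2,0.146529878860814
"EXAMPLE01","tissue",3,0.220859335319235
"EXAMPLE01","tissue",4,0.295888080497509
"EXAMPLE01","tissue",5,0.371632033220403
"EXAMPLE01","tissue",6,0.448108336345037
"EXAMPLE01","tissue",7,0.525335154657696
"EXAMPLE01","tissue",8,0.603331472653872
"EXAMPLE01","tissue",9,0.682117164616174
"EXAMPLE01","tissue",10,0.761713006646653
"EXAMPLE01","tissue",11,0.84214063936174
"EXAMPLE01","tissue",12,0.923422709065493
"EXAMPLE01","tissue",13,1.00558281766652
"EXAMPLE01","tissue",14,1.08864565364409
"EXAMPLE01","tissue",15,1.17263701940231
"EXAMPLE01","tissue",16,1.25758389976919
"EXAMPLE01","tissue",17,1.34351453604293
"EXAMPLE01","tissue",18,1.43045850655946
"EXAMPLE01","tissue",19,1.51844681217988
"EXAMPLE01","tissue",20,1.60751196772008
"EXAMPLE01","tissue",21,1.69768809986044
"EXAMPLE01","tissue",22,1.78901105341472
"EXAMPLE01","tissue",23,1.8815185687787
"EXAMPLE01","tissue",24,1.97525026448653
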