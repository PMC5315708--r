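t,kind
0,head_in
0.9381746233947638,camera_start
1.608548616481292,camera_stop
1.7294649148744063,camera_start
2.3820084592204527,camera_stop
3.9712857477813075,camera_start
7.0287641200387805,camera_stop
11.38189081293223,camera_start
12.522122256905991,camera_stop
18.5761021399089,camera_start
20.824391376519127,camera_stop
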