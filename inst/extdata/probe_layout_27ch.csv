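channel,mni_x,mni_y,mni_z,region,overlap,brodmann
1,47,27,47,Dorsolateral prefrontal cortex,0.63,9
2,25,42,50,Includes frontal eye fields,0.79,8
3,2,47,50,Includes frontal eye fields,0.75,8
4,-20,43,51,Includes frontal eye fields,0.83,8
5,-42,28,48,Includes frontal eye fields,0.61,8
6,55,27,34,Dorsolateral prefrontal cortex,0.90,46
7,38,45,38,Dorsolateral prefrontal cortex,0.69,9
8,15,57,41,Dorsolateral prefrontal cortex,0.83,9
9,-11,58,41,Dorsolateral prefrontal cortex,0.85,9
10,-33,48,38,Dorsolateral prefrontal cortex,0.80,9
11,-50,30,35,Dorsolateral prefrontal cortex,0.51,46
12,48,45,27,Frontopolar area,0.72,10
13,27,60,29,Frontopolar area,0.92,10
14,6,65,31,Frontopolar area,0.90,10
15,-21,62,29,Frontopolar area,0.84,10
16,-42,48,26,Dorsolateral prefrontal cortex,0.66,46
17,56,39,12,Dorsolateral prefrontal cortex,0.39,46
18,41,60,16,Frontopolar area,1,10
19,18,71,19,Frontopolar area,1,10
20,-14,71,17,Frontopolar area,1,10
21,-34,62,15,Frontopolar area,0.97,10
22,-51,44,10,Dorsolateral prefrontal cortex,0.56,46
23,48,55,1,Frontopolar area,0.88,10
24,29,69,6,Frontopolar area,1,10
25,3,70,6,Frontopolar area,1,10
26,-23,71,4,Frontopolar area,1,10
27,-42,59,-1,Frontopolar area,0.78,10
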