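compound_id,cem_ic50,cem_sd,hela_ic50,hela_sd,a549_ic50,a549_sd,mcf7_ic50,mcf7_sd
5a,8.9,0.6,20.9,1.8,41.6,2.1,33.6,1.3
6a,8.3,0.4,19.4,1.4,37.7,1.8,31.2,1.5
6b,9.0,0.4,21.2,2.1,42.4,2.3,34.1,1.6
6c,10.0,0.8,23.7,1.5,49.0,2.5,38.2,2.5
6d,7.7,0.3,17.9,0.9,33.5,1.7,28.7,0.8
6e,7.5,0.6,17.3,0.7,32.1,1.6,27.8,1.3
6f,6.7,0.3,15.3,0.5,26.9,1.4,24.5,0.8
6g,11.9,0.8,28.3,2.1,61.3,3.1,45.8,2.2
6h,6.9,0.5,15.8,0.5,28.0,1.5,25.3,1.2
6i,9.5,0.7,22.3,1.2,45.4,2.5,36.0,1.9
6j,13.6,1.3,32.4,2.4,72.3,3.5,52.6,3.8
noscapine,14.5,2.5,24.0,2.9,72.9,4.6,42.3,2.7
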