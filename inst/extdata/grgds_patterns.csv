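# Zonal-pattern descriptors for the GRGDS pentapeptide
id,d1,d2,phi,symmetry
1,13.82,4.39,80.9,cmm
2,12.94,3.91,85.6,p1
3,7.10,4.42,80.8,p1
4,4.76,4.40,80.5,p1
5,12.99,1.47,89.1,p1
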