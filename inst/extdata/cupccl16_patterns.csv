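# Zonal-pattern descriptors for copper perchlorophthalocyanine (CuPcCl16)
# measured basis-vector d-spacings (Å) and inter-vector angles (deg)
id,d1,d2,phi,symmetry
1,7.59,3.75,93.3,p1
2,7.59,3.55,74.5,p1
3,8.51,2.62,95.6,p1
4,12.76,2.97,89.4,2mm
5,12.75,2.65,96.5,p1
6,12.75,2.15,85.9,p1
7,14.15,14.45,68.0,cmm
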