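# Zonal-pattern descriptors for tetragonal hen egg-white lysozyme
# angles fixed to 90 deg as dictated by the mirror symmetry of the patterns
id,d1,d2,phi,symmetry
1,79.06,79.06,90,4
2,77.48,6.46,90,2mm
3,78.99,14.68,90,2mm
4,77.12,9.53,90,2mm
5,78.20,8.52,90,2mm
6,79.64,12.09,90,2mm
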