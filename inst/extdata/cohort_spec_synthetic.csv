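# SYNTHETIC cohort specification (not real patient data). Per-mutation
# median onsets (days) and patient counts constructed once to be jointly
# consistent with the published group-level constraints: 29 DEE17 patients
# with median onset 43 d, 31 NEDIM patients with median 569 d, 13 patients
# carrying biochemically inactive mutations with median 31 d (remaining 16
# DEE17 patients: median 52 d), and each mutation's onset class.
mutation,disorder,n_patients,median_onset_days,sigma_log
G45E,DEE17,2,5,0.5
L199P,DEE17,2,6,0.5
F275S,DEE17,1,7,0.5
I279N,DEE17,1,9,0.5
G40R,DEE17,2,20,0.5
G203R,DEE17,4,30,0.5
Q52P,DEE17,1,31,0.5
Q52R,DEE17,2,43,0.5
D174G,DEE17,2,45,0.5
A227V,DEE17,2,50,0.5
Y231C,DEE17,4,54,0.5
N270H,DEE17,2,60,0.5
S47G,DEE17,4,120,0.5
E237K,NEDIM,4,400,0.5
R209C,NEDIM,10,500,0.5
E246K,NEDIM,9,569,0.5
Q233P,NEDIM,5,900,0.5
C215Y,NEDIM,3,1500,0.5
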