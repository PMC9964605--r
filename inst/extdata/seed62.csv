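name,x,y,z
FP1,-1.028624,3.16578,1.081559
FPZ,0,3.328698,1.081559
FP2,1.028624,3.16578,1.081559
AF3,-1.001807,2.831559,1.796845
AF4,1.001807,2.831559,1.796845
F7,-2.61686,2.057248,1.081559
F5,-2.189871,2.057248,1.795047
F3,-1.574044,2.057248,2.353745
F1,-0.822484,2.057248,2.709474
FZ,0,2.057248,2.831559
F2,0.822484,2.057248,2.709474
F4,1.574044,2.057248,2.353745
F6,2.189871,2.057248,1.795047
F8,2.61686,2.057248,1.081559
FT7,-3.148088,1.081559,1.081559
FC5,-2.668156,1.081559,1.99027
FC3,-1.933914,1.081559,2.709282
FC1,-1.015345,1.081559,3.170064
FCZ,0,1.081559,3.328698
FC2,1.015345,1.081559,3.170064
FC4,1.933914,1.081559,2.709282
FC6,2.668156,1.081559,1.99027
FT8,3.148088,1.081559,1.081559
T7,-3.328698,0,1.081559
C5,-2.831559,0,2.057248
C3,-2.057248,0,2.831559
C1,-1.081559,0,3.328698
CZ,0,0,3.5
C2,1.081559,0,3.328698
C4,2.057248,0,2.831559
C6,2.831559,0,2.057248
T8,3.328698,0,1.081559
TP7,-3.148088,-1.081559,1.081559
CP5,-2.668156,-1.081559,1.99027
CP3,-1.933914,-1.081559,2.709282
CP1,-1.015345,-1.081559,3.170064
CPZ,0,-1.081559,3.328698
CP2,1.015345,-1.081559,3.170064
CP4,1.933914,-1.081559,2.709282
CP6,2.668156,-1.081559,1.99027
TP8,3.148088,-1.081559,1.081559
P7,-2.61686,-2.057248,1.081559
P5,-2.189871,-2.057248,1.795047
P3,-1.574044,-2.057248,2.353745
P1,-0.822484,-2.057248,2.709474
PZ,0,-2.057248,2.831559
P2,0.822484,-2.057248,2.709474
P4,1.574044,-2.057248,2.353745
P6,2.189871,-2.057248,1.795047
P8,2.61686,-2.057248,1.081559
PO7,-1.75,-2.831559,1.081559
PO5,-1.421625,-2.831559,1.487028
PO3,-1.001807,-2.831559,1.796845
POZ,0,-2.831559,2.057248
PO4,1.001807,-2.831559,1.796845
PO6,1.421625,-2.831559,1.487028
PO8,1.75,-2.831559,1.081559
CB1,-2.03192,-2.796698,-0.547521
O1,-1.028624,-3.16578,1.081559
OZ,0,-3.328698,1.081559
O2,1.028624,-3.16578,1.081559
CB2,2.03192,-2.796698,-0.547521
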