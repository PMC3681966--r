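label	x	y
FPZ	0	1
FZ	0	0.6
FCZ	0	0.4
CZ	0	0
CPZ	0	-0.4
PZ	0	-0.6
POZ	0	-0.8
OZ	0	-1
FP2	0.309	0.9511
AF8	0.5878	0.809
F8	0.809	0.5878
FT8	0.9511	0.309
T8	1	0
TP8	0.9511	-0.309
P8	0.809	-0.5878
PO8	0.5878	-0.809
O2	0.309	-0.9511
FP1	-0.309	0.9511
AF7	-0.5878	0.809
F7	-0.809	0.5878
FT7	-0.9511	0.309
T7	-1	0
TP7	-0.9511	-0.309
P7	-0.809	-0.5878
PO7	-0.5878	-0.809
O1	-0.309	-0.9511
AF3	-0.2939	0.8045
AF4	0.2939	0.8045
F1	-0.2023	0.5969
F3	-0.4045	0.5939
F5	-0.6068	0.5908
F2	0.2023	0.5969
F4	0.4045	0.5939
F6	0.6068	0.5908
FC1	-0.2378	0.3773
FC3	-0.4755	0.3545
FC5	-0.7133	0.3318
FC2	0.2378	0.3773
FC4	0.4755	0.3545
FC6	0.7133	0.3318
C1	-0.25	0
C3	-0.5	0
C5	-0.75	0
C2	0.25	0
C4	0.5	0
C6	0.75	0
CP1	-0.2378	-0.3773
CP3	-0.4755	-0.3545
CP5	-0.7133	-0.3318
CP2	0.2378	-0.3773
CP4	0.4755	-0.3545
CP6	0.7133	-0.3318
P1	-0.2023	-0.5969
P3	-0.4045	-0.5939
P5	-0.6068	-0.5908
P2	0.2023	-0.5969
P4	0.4045	-0.5939
P6	0.6068	-0.5908
PO3	-0.2939	-0.8045
PO5	-0.4408	-0.8068
PO4	0.2939	-0.8045
PO6	0.4408	-0.8068
PO9	-0.676	-0.9304
PO10	0.676	-0.9304
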