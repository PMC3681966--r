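label	x	y
FPZ	0	1
AFZ	0	0.8
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
AFF1h	-0.0873	0.6998
AFF2h	0.0873	0.6998
AFF3h	-0.2619	0.6994
AFF4h	0.2619	0.6994
AFF5h	-0.4365	0.699
AFF6h	0.4365	0.699
AFF7h	-0.6111	0.6986
AFF8h	0.6111	0.6986
FFC1h	-0.11	0.4936
FFC2h	0.11	0.4936
FFC3h	-0.33	0.4807
FFC4h	0.33	0.4807
FFC5h	-0.55	0.4678
FFC6h	0.55	0.4678
FFT7h	-0.77	0.4549
FFT8h	0.77	0.4549
FCC1h	-0.1219	0.1943
FCC2h	0.1219	0.1943
FCC3h	-0.3658	0.1829
FCC4h	0.3658	0.1829
FCC5h	-0.6097	0.1716
FCC6h	0.6097	0.1716
FTT7h	-0.8536	0.1602
FTT8h	0.8536	0.1602
CCP1h	-0.1219	-0.1943
CCP2h	0.1219	-0.1943
CCP3h	-0.3658	-0.1829
CCP4h	0.3658	-0.1829
CCP5h	-0.6097	-0.1716
CCP6h	0.6097	-0.1716
TTP7h	-0.8536	-0.1602
TTP8h	0.8536	-0.1602
CPP1h	-0.11	-0.4936
CPP2h	0.11	-0.4936
CPP3h	-0.33	-0.4807
CPP4h	0.33	-0.4807
CPP5h	-0.55	-0.4678
CPP6h	0.55	-0.4678
TPP7h	-0.77	-0.4549
TPP8h	0.77	-0.4549
PPO1h	-0.0873	-0.6998
PPO2h	0.0873	-0.6998
PPO3h	-0.2619	-0.6994
PPO4h	0.2619	-0.6994
PPO5h	-0.4365	-0.699
PPO6h	0.4365	-0.699
PPO7h	-0.6111	-0.6986
PPO8h	0.6111	-0.6986
POO1h	-0.0561	-0.8975
POO2h	0.0561	-0.8975
POO3h	-0.1682	-0.8925
POO4h	0.1682	-0.8925
POO5h	-0.2803	-0.8875
POO6h	0.2803	-0.8875
POO7h	-0.3924	-0.8825
POO8h	0.3924	-0.8825
I1	-0.3554	-1.0937
IZ	0	-1.15
I2	0.3554	-1.0937
PPO9h	-0.7637	-0.7637
PPO10h	0.7637	-0.7637
P9	-0.9304	-0.676
P10	0.9304	-0.676
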