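Fp1	-0.2938926261	0.9045084972	0.3090169944
Fpz	0.0000000000	0.9510565163	0.3090169944
Fp2	0.2938926261	0.9045084972	0.3090169944
F7	-0.7694208843	0.5590169944	0.3090169944
F3	-0.4330274292	0.6454163629	0.6292256862
Fz	0.0000000000	0.5877852523	0.8090169944
F4	0.4330274292	0.6454163629	0.6292256862
F8	0.7694208843	0.5590169944	0.3090169944
FT7	-0.8999833694	0.2924223230	0.3232941691
FC3	-0.5435422435	0.3436586009	0.7658071530
FCz	0.0000000000	0.3090169944	0.9510565163
FC4	0.5435422435	0.3436586009	0.7658071530
FT8	0.8999833694	0.2924223230	0.3232941691
T7	-0.9510565163	0.0000000000	0.3090169944
C3	-0.5877852523	0.0000000000	0.8090169944
Cz	0.0000000000	0.0000000000	1.0000000000
C4	0.5877852523	0.0000000000	0.8090169944
T8	0.9510565163	0.0000000000	0.3090169944
TP7	-0.8999833694	-0.2924223230	0.3232941691
CP3	-0.5435422435	-0.3436586009	0.7658071530
CPz	0.0000000000	-0.3090169944	0.9510565163
CP4	0.5435422435	-0.3436586009	0.7658071530
TP8	0.8999833694	-0.2924223230	0.3232941691
P7	-0.7694208843	-0.5590169944	0.3090169944
P3	-0.4330274292	-0.6454163629	0.6292256862
Pz	0.0000000000	-0.5877852523	0.8090169944
P4	0.4330274292	-0.6454163629	0.6292256862
P8	0.7694208843	-0.5590169944	0.3090169944
O1	-0.2938926261	-0.9045084972	0.3090169944
Oz	0.0000000000	-0.9510565163	0.3090169944
O2	0.2938926261	-0.9045084972	0.3090169944
POz	0.0000000000	-0.8090169944	0.5877852523
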