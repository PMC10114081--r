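channel	flat	bap_id_like	background_id_like
1:Del:C:0	0.0120481927710843	0.1125	0.0625
1:Del:C:1	0.0120481927710843	0.135	0.075
1:Del:C:2	0.0120481927710843	0.09	0.05
1:Del:C:3	0.0120481927710843	0.054	0.03
1:Del:C:4	0.0120481927710843	0.036	0.02
1:Del:C:5	0.0120481927710843	0.0225	0.0125
1:Del:T:0	0.0120481927710843	0.075	0.1
1:Del:T:1	0.0120481927710843	0.09	0.12
1:Del:T:2	0.0120481927710843	0.06	0.08
1:Del:T:3	0.0120481927710843	0.036	0.048
1:Del:T:4	0.0120481927710843	0.024	0.032
1:Del:T:5	0.0120481927710843	0.015	0.02
1:Ins:C:0	0.0120481927710843	0	0.0375
1:Ins:C:1	0.0120481927710843	0	0.045
1:Ins:C:2	0.0120481927710843	0	0.03
1:Ins:C:3	0.0120481927710843	0	0.018
1:Ins:C:4	0.0120481927710843	0	0.012
1:Ins:C:5	0.0120481927710843	0	0.0075
1:Ins:T:0	0.0120481927710843	0.0625	0.05
1:Ins:T:1	0.0120481927710843	0.075	0.06
1:Ins:T:2	0.0120481927710843	0.05	0.04
1:Ins:T:3	0.0120481927710843	0.03	0.024
1:Ins:T:4	0.0120481927710843	0.02	0.016
1:Ins:T:5	0.0120481927710843	0.0125	0.01
2:Del:R:0	0.0120481927710843	0	0
2:Del:R:1	0.0120481927710843	0	0
2:Del:R:2	0.0120481927710843	0	0
2:Del:R:3	0.0120481927710843	0	0
2:Del:R:4	0.0120481927710843	0	0
2:Del:R:5	0.0120481927710843	0	0
3:Del:R:0	0.0120481927710843	0	0
3:Del:R:1	0.0120481927710843	0	0
3:Del:R:2	0.0120481927710843	0	0
3:Del:R:3	0.0120481927710843	0	0
3:Del:R:4	0.0120481927710843	0	0
3:Del:R:5	0.0120481927710843	0	0
4:Del:R:0	0.0120481927710843	0	0
4:Del:R:1	0.0120481927710843	0	0
4:Del:R:2	0.0120481927710843	0	0
4:Del:R:3	0.0120481927710843	0	0
4:Del:R:4	0.0120481927710843	0	0
4:Del:R:5	0.0120481927710843	0	0
5:Del:R:0	0.0120481927710843	0	0
5:Del:R:1	0.0120481927710843	0	0
5:Del:R:2	0.0120481927710843	0	0
5:Del:R:3	0.0120481927710843	0	0
5:Del:R:4	0.0120481927710843	0	0
5:Del:R:5	0.0120481927710843	0	0
2:Ins:R:0	0.0120481927710843	0	0
2:Ins:R:1	0.0120481927710843	0	0
2:Ins:R:2	0.0120481927710843	0	0
2:Ins:R:3	0.0120481927710843	0	0
2:Ins:R:4	0.0120481927710843	0	0
2:Ins:R:5	0.0120481927710843	0	0
3:Ins:R:0	0.0120481927710843	0	0
3:Ins:R:1	0.0120481927710843	0	0
3:Ins:R:2	0.0120481927710843	0	0
3:Ins:R:3	0.0120481927710843	0	0
3:Ins:R:4	0.0120481927710843	0	0
3:Ins:R:5	0.0120481927710843	0	0
4:Ins:R:0	0.0120481927710843	0	0
4:Ins:R:1	0.0120481927710843	0	0
4:Ins:R:2	0.0120481927710843	0	0
4:Ins:R:3	0.0120481927710843	0	0
4:Ins:R:4	0.0120481927710843	0	0
4:Ins:R:5	0.0120481927710843	0	0
5:Ins:R:0	0.0120481927710843	0	0
5:Ins:R:1	0.0120481927710843	0	0
5:Ins:R:2	0.0120481927710843	0	0
5:Ins:R:3	0.0120481927710843	0	0
5:Ins:R:4	0.0120481927710843	0	0
5:Ins:R:5	0.0120481927710843	0	0
2:Del:M:1	0.0120481927710843	0	0
3:Del:M:1	0.0120481927710843	0	0
3:Del:M:2	0.0120481927710843	0	0
4:Del:M:1	0.0120481927710843	0	0
4:Del:M:2	0.0120481927710843	0	0
4:Del:M:3	0.0120481927710843	0	0
5:Del:M:1	0.0120481927710843	0	0
5:Del:M:2	0.0120481927710843	0	0
5:Del:M:3	0.0120481927710843	0	0
5:Del:M:4	0.0120481927710843	0	0
5:Del:M:5	0.0120481927710843	0	0
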