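region	Met408Val	Pro341Leu	Phe160Leu	Arg342His	Gly414Ala
Sub-Saharan Africa	0.73	0.033	0.045	0.02	0.001
North Africa and Middle East	0.57	0.015	0	0.002	0
Europe	0.55	0.018	0.135	0	0.02
Central Asia	0.52	0.09	0.11	0.002	0
East Asia and Oceania	0.74	0.145	0.155	0	0
America	0.92	0.004	0	0	0
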