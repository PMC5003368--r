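t_ms,button,edge
11985,plane_ventral,press
12005,plane_ventral,release
22943,plane_dorsal,press
22963,plane_dorsal,release
25454,sample_down,press
25474,sample_down,release
41575,sample_down,press
41595,sample_down,release
53991,plane_ventral,press
54011,plane_ventral,release
55138,sample_down,press
55158,sample_down,release
55596,plane_dorsal,press
55616,plane_dorsal,release
72763,plane_ventral,press
72783,plane_ventral,release
77025,sample_up,press
77045,sample_up,release
78688,plane_dorsal,press
78708,plane_dorsal,release
94623,plane_dorsal,press
94643,plane_dorsal,release
97140,sample_up,press
97160,sample_up,release
104275,plane_dorsal,press
104295,plane_dorsal,release
118915,sample_down,press
118935,sample_down,release
126507,plane_dorsal,press
126527,plane_dorsal,release
128884,stack,press
128904,stack,release
136997,plane_dorsal,press
137017,plane_dorsal,release
137795,plane_ventral,press
137815,plane_ventral,release
149904,plane_dorsal,press
149924,plane_dorsal,release
150377,sample_up,press
150397,sample_up,release
152273,info,press
152293,info,release
158003,plane_ventral,press
158023,plane_ventral,release
159040,plane_ventral,press
159060,plane_ventral,release
166821,plane_dorsal,press
166841,plane_dorsal,release
179189,plane_dorsal,press
179209,plane_dorsal,release
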