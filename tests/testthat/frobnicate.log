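psmfkin frobnicate | R 4.3.3 | 2026-09-19 08:36:24 
psmfkin frobnicate | R 4.3.3 | 2026-09-19 08:38:01 
psmfkin frobnicate | R 4.3.3 | 2026-09-19 08:39:05 
psmfkin frobnicate | R 4.3.3 | 2026-09-19 08:44:05 
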