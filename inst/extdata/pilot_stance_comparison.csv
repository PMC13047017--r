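side_detected,side_correct,stance_detected,stance_expert,knee_left_deg,shin_left_deg,knee_right_deg,shin_right_deg,parse_ambiguous
right,yes,zenkutsu,zenkutsu,91,44,65,63,FALSE
left,yes,zenkutsu,zenkutsu,33,91,11,136,TRUE
left,no,kiba,kiba,34,105,25,105,FALSE
left,yes,kokutsu,kokutsu,16,109,13,102,FALSE
right,yes,zenkutsu,zenkutsu,11,61,70,121,TRUE
left,yes,zenkutsu,zenkutsu,38,94,29,110,FALSE
left,yes,kokutsu,kokutsu,33,97,13,130,FALSE
left,yes,kiba,kiba,45,120,26,107,FALSE
right,yes,kokutsu,kokutsu,7,118,18,115,FALSE
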