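# Approximate transcription (synthetic stand-in) of the 63-note choral theme
# from the finale of Beethoven's ninth symphony. Durations in crotchet units.
pitch	duration
F#4	1
F#4	1
G4	1
A4	1
A4	1
G4	1
F#4	1
E4	1
D4	1
D4	1
E4	1
F#4	1
F#4	1.5
E4	0.5
E4	2
F#4	1
F#4	1
G4	1
A4	1
A4	1
G4	1
F#4	1
E4	1
D4	1
D4	1
E4	1
F#4	1
E4	1.5
D4	0.5
D4	2
E4	1
E4	1
F#4	1
D4	1
E4	1
F#4	0.5
G4	0.5
F#4	1
D4	1
E4	1
F#4	0.5
G4	0.5
F#4	1
E4	1
D4	1
E4	1
A3	2
F#4	1
F#4	1
F#4	1
G4	1
A4	1
A4	1
G4	1
F#4	1
E4	1
D4	1
D4	1
E4	1
F#4	1
E4	1.5
D4	0.5
D4	2
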