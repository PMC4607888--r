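# Approximate transcription (synthetic stand-in) of an 86-note rendering of
# the motif from Wagner's 'Ride of the Valkyries'. Durations in crotchet units.
pitch	duration
F#3	0.5
B3	0.25
F#3	0.75
B3	0.5
D4	1
B3	0.5
D4	0.25
B3	0.75
D4	0.5
F#4	1
D4	0.5
F#4	0.25
D4	0.75
F#4	0.5
B4	1
F#4	0.5
B4	0.25
F#4	0.75
B4	0.5
D5	1
A3	0.5
D4	0.25
A3	0.75
D4	0.5
F#4	1
D4	0.5
F#4	0.25
D4	0.75
F#4	0.5
A4	1
F#4	0.5
A4	0.25
F#4	0.75
A4	0.5
D5	1
A4	0.5
D5	0.25
A4	0.75
D5	0.5
F#5	1
B3	0.5
E4	0.25
B3	0.75
E4	0.5
G4	1
E4	0.5
G4	0.25
E4	0.75
G4	0.5
B4	1
G4	0.5
B4	0.25
G4	0.75
B4	0.5
E5	1
B4	0.5
E5	0.25
B4	0.75
E5	0.5
G5	1
F#3	0.5
B3	0.25
F#3	0.75
B3	0.5
D4	1
B3	0.5
D4	0.25
B3	0.75
D4	0.5
F#4	1
D4	0.5
F#4	0.25
D4	0.75
F#4	0.5
B4	1
F#4	0.5
B4	0.25
F#4	0.75
B4	0.5
D5	1
B4	0.5
D5	0.25
B4	0.75
D5	0.5
F#5	1
B4	3
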