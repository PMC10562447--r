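# Canonical sigma-70 seed: -35 and -10 consensus hexamers with a 17 bp
# spacer inside a 165 bp design window (0-based starts).
window_length: 165
label: sigma70 canonical
motifs:
- seq: TTGACA
  start: 120
- seq: TATAAT
  start: 143
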