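node Y 1 1
node Z 1 1
input X 0.5
edge X Y + 0.3 2
edge Y Y + 0.3 2
edge X Z + 0.05 2
edge Y Z - 0.15 2
gate Y AND
gate Z AND
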