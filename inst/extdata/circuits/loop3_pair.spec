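node X 1.5 1
node Y 1.5 1
node Z 1.5 1
node W 1.5 1
edge X Y + 0.3 4
edge Y Z - 0.3 4
edge Z X + 0.3 4
edge Y W + 0.3 4
edge W X + 0.3 4
gate X AND
gate Y AND
gate Z AND
gate W AND
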