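node X 1 1
node Y 1 1
edge Y X - 0.3 2
edge X Y - 0.3 2
gate X AND
gate Y AND
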