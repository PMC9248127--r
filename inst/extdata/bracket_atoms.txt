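# Bracket-atom inventory attachable during category 3/4 corpus generation,
# one entry per line.
[Pb]
[NH]
[Ru]
[Li]
[K]
[Si]
[S+]
[O]
[O-]
[N+]
[N]
[P]
[C]
[H]
[2H]
[3H]
[B]
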