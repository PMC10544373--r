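# Curated starter list of genera reported as cellulolytic / fibrolytic in
# ruminant gut literature; user-editable, one genus per line.
Ruminococcus
Fibrobacter
Prevotella
Butyrivibrio
Pseudobutyrivibrio
Bacteroides
Clostridium
Cellulomonas
Cellvibrio
Eubacterium
Treponema_D
Lachnospira
Oscillibacter
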