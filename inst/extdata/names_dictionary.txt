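# Synthetic person-name dictionary (stand-in for a large common-names list).
# One name per line, matched case-insensitively on word boundaries.
mary
john
susan
karen
linda
david
michael
sarah
emma
james
patricia
jennifer
robert
william
elizabeth
barbara
margaret
dorothy
helen
ruth
laura
kevin
brian
nancy
betty
sandra
donna
carol
michelle
amanda
melissa
deborah
stephanie
rebecca
sharon
cynthia
kathleen
angela
anna
pamela
nicole
samantha
katherine
christine
debra
rachel
carolyn
janet
maria
heather
diane
julie
joyce
victoria
kelly
christina
joan
evelyn
judith
gregory
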