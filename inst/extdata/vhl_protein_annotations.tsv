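hgvs_c	hgvs_p
c.217C>T	p.Gln73Ter
c.292T>C	p.Tyr98His
c.388G>A	p.Val130Ile
c.429C>T	p.Asp143=
c.562C>G	p.Leu188Val
c.598C>T	p.Arg200Trp
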