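species	T	W	C
sp01	2	?	?
sp02	2	2	?
sp03	?	2	?
sp04	0	2	1
sp05	?	2	?
sp06	?	2	2
sp07	?	?	2
sp08	?	2	2
sp09	?	?	2
sp10	2	?	?
sp11	?	2	?
sp12	2	1	?
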