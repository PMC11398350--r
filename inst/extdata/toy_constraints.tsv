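species	biome	action
sp01	C	exclude
sp03	C	include
sp07	T	exclude
sp09	T	exclude
sp11	C	include
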