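(((sp01:0.18,sp02:0.18):0.42,((sp03:0.25,sp04:0.25):0.2,(sp05:0.3,sp06:0.3):0.15):0.15):0.4,((sp07:0.35,(sp08:0.2,sp09:0.2):0.15):0.4,(sp10:0.5,(sp11:0.28,sp12:0.28):0.22):0.25):0.25);
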