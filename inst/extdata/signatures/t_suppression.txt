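CD274
PDCD1LG2
IDO1
IL10
ARG1
NOS2
LGALS9
TGFB1
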