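# Table-style default parameter objects shared across tests
rp0 <- radiosensitivity_params()
lp0 <- leukemogenesis_params()
mp0 <- mortality_params()
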