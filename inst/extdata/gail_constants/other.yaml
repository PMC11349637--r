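# Gail-model constant block: other / unknown race-ethnicity.
# NCI convention: unknown race is scored with the White block.
version: "1.0"
race_group: other
alias: white
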