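# packaged region configuration (1-based rCRS coordinates)
region_start=648
region_end=1601
amplicon_start=618
amplicon_end=2007
human_id=Homo_sapiens
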