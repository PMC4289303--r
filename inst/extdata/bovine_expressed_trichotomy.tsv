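# Unique expressed bovine TRA/TRD V sequences by identity class against the
# UMD3.1 genomic V-gene catalog (identical; 97.0-99.5%; below 97%).
category	n
identical	67
allelic_or_unassembled	103
novel	21
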