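>synthetic_mixed_protein example amino-acid FASTA accepted by read_sequence_fasta
MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYN
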