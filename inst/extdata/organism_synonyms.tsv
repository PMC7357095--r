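synonym	canonical
human	human
homo sapiens	human
h. sapiens	human
hsapiens	human
mouse	mouse
mus musculus	mouse
m. musculus	mouse
rat	rat
rattus norvegicus	rat
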