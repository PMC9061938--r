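# Phage-related product keywords, one phrase per line.
# Lines starting with '-' veto a match (exclude phrases).
integrase
transposase
terminase
portal
capsid
head
tail
fiber
baseplate
coat
virion
lysin
lysozyme
holin
protease
tape measure
antirepressor
phage
prophage
recombinase
-crispr
-transferase inhibitor
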