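# Antigen-binding-site codon positions (1-based codon indices relative to
# the analysed class IIB exon 2 fragment), derived from the beta-chain
# peptide-contact residues of the human class II molecular structure and
# mapped onto the amplified window (62 codons). Antigen-binding-site
# inference depends on the structural reference and on primer placement, so
# edit this list to match your alignment before interpreting partitioned
# dN/dS estimates.
3
5
7
20
22
24
26
31
32
37
38
47
50
51
53
55
56
57
58
60
61
62
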