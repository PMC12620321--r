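type	enzyme	sizes
Type1	NaeI	487,242
Type1	SfaNI	276,225,121,59,48
Type2	NaeI	729
Type2	SfaNI	397,225,59,48
Type3	NaeI	729
Type3	SfaNI	276,225,121,59,48
Type4	NaeI	729
Type4	SfaNI	225,146,130,121,59,48
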