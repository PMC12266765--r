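locus	allele	status
MT-TL1	A3243G	Cfrm
MT-TK	A8344G	Cfrm
MT-ATP6	T8993G	Cfrm
MT-ATP6	T8993C	Cfrm
MT-ATP6	T9176C	Cfrm
MT-ND1	G3460A	Cfrm
MT-ND4	G11778A	Cfrm
MT-ND6	T14484C	Cfrm
MT-TS1	T7511C	Cfrm
MT-TI	A4300G	Cfrm
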