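kind	id	name	organism	sequence
uniprot	P00722	beta-galactosidase	Escherichia coli	MTMITDSLAVVLQRRDWENPGVTQLNRLAAHPPFASWRN
name		beta-galactosidase	Escherichia coli	MTMITDSLAVVLQRRDWENPGVTQLNRLAAHPPFASWRN
name		alkaline phosphatase	Escherichia coli	MKQSTIALALLPLLFTPVTKA
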