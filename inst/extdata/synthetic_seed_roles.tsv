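seed_id	role
SYN_PHNW	PhnW
SYN_PHNX	PhnX
SYN_PHNY	PhnY
SYN_PHNA	PhnA
SYN_PBFA	PbfA
SYN_PBFC	PbfC
SYN_PBFD	PbfD
SYN_PBFF	PbfF
SYN_TRANSPORTER	transporter
SYN_REGULATOR	regulator
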