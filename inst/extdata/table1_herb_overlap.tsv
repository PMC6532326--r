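herb	ingredient	ob	dl
CT	beta-sitosterol
CL	beta-sitosterol
OF	beta-sitosterol
PGS	beta-sitosterol
RC	beta-sitosterol
RP	beta-sitosterol
RS	beta-sitosterol
CT	sitosterol
OF	sitosterol
PGS	sitosterol
RP	sitosterol
RS	sitosterol
RCX	sitosterol
SM	quercetin
AgR	quercetin
OF	quercetin
RC	quercetin
SP	quercetin
SM	stigmasterol
CL	stigmasterol
RP	stigmasterol
AgR	acetic acid
CT	acetic acid
RP	acetic acid
AgR	kaempferol
OF	kaempferol
RM	kaempferol
SM	(-)-taxifolin
CT	(-)-taxifolin
SM	CLR
CL	CLR
AgR	hederagenin
CL	hederagenin
AgR	FA
RCX	FA
CT	(+)-catechin
RP	(+)-catechin
PGS	baicalein
RP	baicalein
RC	ecdysterone
RM	ecdysterone
RS	mandanol
RCX	mandanol
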