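name	formula	adduct	exchange_sites	site_probs	charge_site	abundance
codeine	C18H21NO3	[M+H]+	hydroxyl:1		TRUE	60
hydrocodone	C18H21NO3	[M+H]+			TRUE	60
6-acetylmorphine	C19H21NO4	[M+H]+	phenol:1		TRUE	50
naloxone	C19H21NO4	[M+H]+	phenol:1;hydroxyl:1		TRUE	50
morphine	C17H19NO3	[M+H]+	phenol:1;hydroxyl:1	phenol:0.13;hydroxyl:0.20	TRUE	55
norcodeine	C17H19NO3	[M+H]+	hydroxyl:1;imine_NH:1		TRUE	55
glucose	C6H12O6	[M+H]+	hydroxyl:5		FALSE	90
inositol	C6H12O6	[M+H]+	hydroxyl:6		FALSE	70
urea	CH4N2O	[2M+H]+	amide_NH:4		TRUE	100
creatinine	C4H7N3O	[M+H]+	amine:2;amide_NH:1		TRUE	95
sphingosine	C18H37NO2	[M+H]+	hydroxyl:2;amine:2		TRUE	40
palmitoylethanolamide	C18H37NO2	[M+Na]+	hydroxyl:1;amide_NH:1		FALSE	35
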