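variant	edit_distance
dfluoxetina	1
flluoxetina	1
floxetina	1
fluoexetina	1
fluoixetina	1
fluopxetina	1
fluoxertina	1
fluoxetiina	1
fluoxetijna	1
fluoxetin	1
fluoxetinas	1
fluoxetna	1
fluoxetona	1
fluoxettina	1
fluoxetuina	1
fluoxewtina	1
fluoxtina	1
fluozxetina	1
fluuoxetina	1
fluxetina	1
fluyoxetina	1
flhuoxetin	2
flluoxetin	2
flouxetina	2
fluoxeitna	2
fluoxetian	2
fluxoetina	2
fluxotina	2
fluloextina	3
fluoxetinaate	3
fluoxetinapor	3
flxtina	3
fluoxetinapara	4
infloexetina	4
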