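# crtEBI elementary reaction network
Idi + IPP <-> Idi_IPP | kf1 kr1 | Idi 1
Idi_IPP <-> Idi + DMAPP | kf2 kr2 | Idi 1
IspA + DMAPP <-> IspA_DMAPP | kf3 kr3 | IspA 2
IspA_DMAPP + IPP <-> IspA_DMAPP_IPP | kf4 kr4 | IspA 2
IspA_DMAPP_IPP <-> IspA + GPP | kf5 kr5 | IspA 2
IspA + GPP <-> IspA_GPP | kf6 kr6 | IspA 3
IspA_GPP + IPP <-> IspA_GPP_IPP | kf7 kr7 | IspA 3
IspA_GPP_IPP <-> IspA + FPP | kf8 kr8 | IspA 3
CrtE + GPP <-> CrtE_GPP | kf9 kr9 | CrtE 4
CrtE_GPP + IPP <-> CrtE_GPP_IPP | kf10 kr10 | CrtE 4
CrtE_GPP_IPP <-> CrtE + FPP | kf11 kr11 | CrtE 4
CrtE + FPP <-> CrtE_FPP | kf12 kr12 | CrtE 5
CrtE_FPP + IPP <-> CrtE_FPP_IPP | kf13 kr13 | CrtE 5
CrtE_FPP_IPP <-> CrtE + GGPP | kf14 kr14 | CrtE 5
CrtB + GGPP <-> CrtB_GGPP | kf15 kr15 | CrtB 6
CrtB_GGPP + GGPP <-> CrtB_PPPP | kf16 kr16 | CrtB 6
CrtB_PPPP <-> CrtB_phytoene | kf17 kr17 | CrtB 7
CrtB_phytoene <-> CrtB + phytoene | kf18 kr18 | CrtB 7
CrtI + phytoene <-> CrtI_phytoene | kf19 kr19 | CrtI 8
CrtI_phytoene <-> CrtI + phytofluene | kf20 kr20 | CrtI 8
CrtI + phytofluene <-> CrtI_phytofluene | kf21 kr21 | CrtI 9
CrtI_phytofluene <-> CrtI + zeta_carotene | kf22 kr22 | CrtI 9
CrtI + zeta_carotene <-> CrtI_zeta | kf23 kr23 | CrtI 10
CrtI_zeta <-> CrtI + neurosporene | kf24 kr24 | CrtI 10
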