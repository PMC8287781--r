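gene_id,marker_class
C3,A1
Fbln5,A1
H2-T23,A1
Serping1,A1
Srgn,A1
Gbp2,A1
Psmb8,A1
Emp1,A2
Ptx3,A2
Tm4sf1,A2
S100a10,A2
Cd109,A2
Clcf1,A2
Tgm1,A2
Serpina3n,PAN_reactive
Steap4,PAN_reactive
Timp1,PAN_reactive
Vim,PAN_reactive
Lcn2,PAN_reactive
Gfap,PAN_reactive
Cxcl10,PAN_reactive
Apoe,DAM
Axl,DAM
Clec7a,DAM
Tyrobp,DAM
Trem2,DAM
C4a,reactive_oligodendrocyte
Serpina3n,reactive_oligodendrocyte
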