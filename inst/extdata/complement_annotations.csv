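gene_id,complement_class,complement_pathway
C1qa,initiator,classical
C1qb,initiator,classical
C1qc,initiator,classical
C4a,effector,classical
Serping1,regulator,classical
C3,effector,effector
C3ar1,receptor,effector
C5ar1,receptor,effector
Itgam,receptor,effector
Itgax,receptor,effector
C6,effector,terminal
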