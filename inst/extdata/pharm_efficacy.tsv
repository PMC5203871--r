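compound	pharmacology	effect
saikosaponin_a	Increasing IL-2 and IgM level	qi_dispersing
saikosaponin_a	Reducing LPO	qi_dispersing
saikosaponin_a	Keeping a balance of TH/TS	blood_nourishing
saikosaponin_d	Increasing IL-2 and IgM level	qi_dispersing
saikosaponin_d	Reducing LPO	qi_dispersing
saikosaponin_d	Keeping a balance of TH/TS	blood_nourishing
ferulic_acid	Decreasing LPO and MDA	qi_dispersing
ferulic_acid	Balancing TXA2/PGI2	qi_dispersing
ferulic_acid	Reducing blood viscosity	qi_dispersing
ferulic_acid	Increasing SOD activity	spleen_invigorating
ferulic_acid	Enhancing hematopoietic function	blood_nourishing
ferulic_acid	Keeping the balance of TXB2/6-keto-PGF1a	spleen_invigorating
ligustilide	Decreasing MDA	qi_dispersing
ligustilide	Balancing TXA2/PGI2	qi_dispersing
ligustilide	Reducing blood viscosity	qi_dispersing
ligustilide	Increasing activity of SOD and GSH-PX	spleen_invigorating
paeoniflorin	Decreasing MDA	qi_dispersing
paeoniflorin	Reducing blood viscosity	qi_dispersing
paeoniflorin	Balancing TXA2/PGI2	qi_dispersing
paeoniflorin	Increasing IL-2 and IgM level	qi_dispersing
paeoniflorin	Keeping a balance of TH/TS	blood_nourishing
paeoniflorin	Increasing activity of SOD and GSH-PX	spleen_invigorating
paeoniflorin	Enhancing hematopoietic function	blood_nourishing
paeoniflorin	Improving the quality of erythrocytes	blood_nourishing
atractylenolide_i	Strengthening digestion and absorption	spleen_invigorating
atractylenolide_i	Enhancing salivary amylase activity	spleen_invigorating
atractylenolide_i	Slowing the heart rate	spleen_invigorating
atractylenolide_iii	Strengthening digestion and absorption	spleen_invigorating
pachyman	Scavenging free radical	qi_dispersing
pachyman	Reducing LPO and MDA	qi_dispersing
pachyman	Lowering blood sugar	qi_dispersing
pachyman	Increasing SOD activity	spleen_invigorating
glycyrrhizin	Decreasing MDA	qi_dispersing
glycyrrhizin	Increasing IL-1b, IL-6 and IL-10	qi_dispersing
glycyrrhizin	Scavenging free radical	qi_dispersing
glycyrrhizin	Increasing SOD activity	spleen_invigorating
glycyrrhizin	Increasing the plasma TP	blood_nourishing
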