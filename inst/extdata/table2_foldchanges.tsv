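mirna_id	PBS/OVA vs PBS/PBS	OVA/OVA vs PBS/PBS	OVA/OVA vs PBS/OVA	OVA/OVA vs OVA/OVA DEX	OVA/OVA DEX vs PBS/PBS
mmu-let-7d-3p	1.32	-1.38	-1.82	-2.60	1.89
mmu-miR-1224-5p	-1.02	2.48	2.54	2.40	1.04
mmu-miR-130b-3p	1.00	2.22	2.21	2.87	-1.30
mmu-miR-135a-1-3p	1.43	3.40	2.37	5.12	-1.51
mmu-miR-135b-5p	3.53	4.86	1.38	4.51	1.08
mmu-miR-139-3p	1.38	3.25	2.36	2.81	1.16
mmu-miR-142-3p	-1.02	1.90	1.93	2.01	-1.06
mmu-miR-144-3p	1.10	-1.47	-1.61	-2.23	1.52
mmu-miR-155-5p	1.01	4.04	4.00	6.66	-1.65
mmu-miR-188-5p	-1.96	3.63	3.12	3.51	-2.99
mmu-miR-1897-5p	1.19	3.12	2.62	2.58	1.21
mmu-miR-18a-5p	1.05	2.33	2.21	2.39	-1.03
mmu-miR-193b-3p	-1.35	-2.29	-1.70	-1.87	-1.22
mmu-miR-21a-5p	1.29	2.77	2.15	2.64	1.05
mmu-miR-223-3p	1.08	2.30	2.12	1.30	1.76
mmu-miR-328-3p	1.13	-1.58	-1.78	-2.56	1.62
mmu-miR-362-5p	1.07	2.95	2.77	2.40	1.23
mmu-miR-378a-3p	-1.13	2.21	2.50	2.29	-1.03
mmu-miR-378a-5p	-1.16	1.52	1.76	2.19	-1.45
mmu-miR-449a-5p	1.20	2.02	1.68	4.19	-2.08
mmu-miR-451a	1.05	-1.59	-1.68	-2.36	1.48
mmu-miR-486-5p	1.01	-1.62	-1.64	-2.44	1.51
mmu-miR-503-5p	-1.14	1.06	1.21	2.62	-2.47
mmu-miR-532-5p	1.02	2.05	2.02	1.94	1.06
mmu-miR-551b-3p	1.34	-1.72	-2.30	-3.74	2.18
mmu-miR-680	1.03	6.24	6.24	6.24	-1.30
mmu-miR-721	1.54	6.31	4.61	6.31	1.70
mmu-miR-7a-5p	1.08	2.12	1.97	2.09	1.01
mmu-miR-877-5p	-1.19	5.14	5.14	5.14	-1.42
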