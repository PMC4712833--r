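signature	gene_id
rod	Rho
rod	Nrl
rod	Nr2e3
rod	Gnat1
rod	Pde6b
cone	Arr3
cone	Opn1sw
cone	Gnat2
cone	Pde6c
retinal_progenitor	Vsx2
retinal_progenitor	Lhx2
retinal_progenitor	Sox2
retinal_progenitor	Hes1
muller_glia	Glul
muller_glia	Rlbp1
muller_glia	Slc1a3
g2m	Ccnb1
g2m	Cdk1
g2m	Plk1
g2m	Top2a
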