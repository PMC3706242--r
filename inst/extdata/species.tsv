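species	initial_value	compartment	description
Glut_lum	1	lumen	native gluten peptides in the intestinal lumen
Glut_lam	0.2	lamina	native gluten peptides in the lamina propria
dGlut	0.2	lamina	deamidated gluten peptides (incl. TG-2 complexes)
Zon	0.2	lumen	zonulin
IEC	0.5	epithelium	mature intestinal epithelial cells
aIEC	0.2	epithelium	activated intestinal epithelial cells
IEL	1	epithelium	resting intraepithelial lymphocytes
aIEL	0.2	epithelium	activated IEL (natural killers)
IL15	0.2	lamina	interleukin-15
IF21	0.2	lamina	merged IFN-gamma + IL-21 pool
APC	0.4	lamina	resting DQ2/DQ8 antigen-presenting cells
aAPC	0.2	lamina	activated DQ2/DQ8 antigen-presenting cells
Tcell	2	lamina	resting T cells (pooled Th1 + Th17)
aTt	0.2	lamina	transiently activated T cells
aT	0.2	lamina	activated T cells
Ab	0.2	plasma	antibodies to gluten peptides and TG-2
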