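name	value	unit	source	ci_lo	ci_hi	description
inflow_gluten_diet	26	au/d	calculated	NA	NA	constant gluten peptide inflow into the lumen, gluten-containing diet
inflow_gfd	0.074	au/d	calculated	NA	NA	constant gluten peptide inflow into the lumen, gluten-free diet (<20 ppm contamination)
kdeg_glum	25	1/d	literature	NA	NA	degradation/clearance of gluten peptides in the lumen
kz_transport	0.4809	1/(au*d)	fitted	0.4328	0.529	zonulin-dependent paracellular transport coefficient (lumen to lamina)
ki_transport	2.119	1/d	fitted	1.907	2.331	epithelial-deficit-dependent transport coefficient (lumen to lamina)
IEC_healthy	1	au	literature	NA	NA	mature IEC level of a healthy subject (villous-area reference)
kdeg_glam	2	1/d	literature	NA	NA	degradation of native gluten peptides in the lamina propria
kcat_deam	20	1/(au*d)	fitted	18	22	TG-2 deamidation rate constant
TG2_level	1	au	literature	NA	NA	tissue transglutaminase level in the lamina propria
kdeg_dglut	4	1/d	literature	NA	NA	degradation of deamidated gluten peptides
kmat	0.2	au/d	literature	NA	NA	IEC maturation (supply) rate
Ki_ab_mat	1000	au	fitted	900	1100	antibody inhibition constant of IEC maturation
kd_iec	0.2	1/d	literature	NA	NA	basal IEC death rate constant
kd_iec_aiel	3.978	1/(au*d)	fitted	3.58	4.376	IEC apoptosis induced by activated IEL (natural killers)
kd_iec_if21	8.135	1/(au*d)	fitted	7.322	8.949	IEC apoptosis induced by IF-21 (IFN-gamma + IL-21)
kd_iec_ab	3e-4	1/(au*d)	fitted	2.7e-4	3.3e-4	IEC apoptosis induced by antibodies
k_act_iec	0.12	1/d	fitted	0.108	0.132	IEC activation rate constant (gluten binding to IEC receptors)
K_act_iec	0.002	au	fitted	0.0018	0.0022	luminal gluten level at half receptor occupancy for IEC activation
h_act_iec	4	dimensionless	literature	NA	NA	Hill coefficient of IEC activation (receptor-occupancy threshold)
kd_aiec	9.898	1/d	fitted	8.908	10.89	basal death rate constant of activated IEC
k_zon	271.2	1/d	fitted	244.1	298.3	zonulin synthesis rate constant per activated IEC
kdeg_zon	5	1/d	literature	NA	NA	zonulin degradation rate constant
k_il15_aiec	4.415	1/d	fitted	3.974	4.857	IL-15 synthesis rate constant per activated IEC
k_il15_aapc	2.238	1/d	fitted	2.014	2.462	IL-15 synthesis rate constant per activated APC
kdeg_il15	2	1/d	literature	NA	NA	IL-15 degradation rate constant
s_iel	0.1	au/d	literature	NA	NA	IEL supply rate into the epithelium
kd_iel	0.1	1/d	literature	NA	NA	resting IEL death rate constant
k_act_iel	0.7079	1/d	fitted	0.6371	0.7787	IEL activation rate constant (IL-15 driven)
K_act_iel	0.3141	au	fitted	0.2827	0.3455	IL-15 level at half-maximal IEL activation
h_act_iel	1.454	dimensionless	assumed	NA	NA	Hill coefficient of IEL activation by IL-15
kd_aiel	1.514	1/d	fitted	1.363	1.665	basal death rate constant of activated IEL
Ki_il15_apop	4.72	au	fitted	4.248	5.192	IL-15 inhibition constant of activated-IEL apoptosis
k_apc_basal	0.09163	au/d	fitted	0.08247	0.1008	IL-15-independent APC differentiation from monocytes
k_apc_il15	0.02556	au/d	fitted	0.023	0.02812	IL-15-stimulated APC differentiation from monocytes
K_apc_il15	0.2131	au	fitted	0.1918	0.2344	IL-15 level at half-maximal APC differentiation
kd_apc	0.1	1/d	literature	NA	NA	death rate constant of resting APC
k_act_apc	1.862	1/d	fitted	1.676	2.048	APC activation rate constant by lamina gluten peptides
EC50_deam	7.063	au	literature	NA	NA	EC50 of APC activation by deamidated peptides
EC50_nat	35.31	au	calculated	NA	NA	EC50 of APC activation by native peptides (5-fold above deamidated)
kd_aapc	0.1811	1/d	fitted	0.163	0.1992	death rate constant of activated APC
s_tcell	0.1	au/d	literature	NA	NA	T-cell supply rate into the lamina propria
kd_tcell	0.05	1/d	literature	NA	NA	resting T-cell death rate constant
k_act_t	0.02378	1/(au*d)	fitted	0.0214	0.02616	T-cell activation rate constant by activated APC
a_if21_t	0.9966	dimensionless	fitted	0.8969	1.096	amplitude of IF-21 stimulation of T-cell activation
K_if21_t	25.12	au	fitted	22.61	27.63	IF-21 level at half-maximal stimulation of T-cell activation
k_trans_t	0.3	1/d	fitted	0.27	0.33	transition rate from transient to fully activated T cells
kd_att	0.02	1/d	assumed	NA	NA	death rate constant of transiently activated T cells
kd_at	0.1442	1/d	fitted	0.1298	0.1586	death rate constant of activated T cells
k_if21_at	1.1	1/d	fitted	0.99	1.21	IF-21 synthesis rate constant per activated T cell
k_if21_aiel	10	1/d	fitted	9	11	IF-21 synthesis rate constant per activated IEL
kdeg_if21	4	1/d	calculated	NA	NA	IF-21 degradation (average of IFN-gamma and IL-21 rates)
ksab	0.001	1/d	fitted	9e-4	0.0011	antibody synthesis rate constant
K_ab_pep	0.1596	au	fitted	0.1436	0.1756	lamina peptide level at half-maximal antibody synthesis
kdeg_ab	0.045	1/d	literature	NA	NA	antibody degradation rate constant
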