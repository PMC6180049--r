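gene	hazard_ratio	p_value	coefficient	ci_low	ci_high
ABCA1	1.064	0.571	0.062	0.858	1.319
AEBP1	1.144	0.025	0.134	1.017	1.287
ALOX5AP	1.023	0.775	0.023	0.875	1.195
CD14	1.41	0.006	0.343	1.101	1.805
CD163	1.027	0.747	0.027	0.872	1.21
CD44	1.13	0.19	0.122	0.941	1.356
CFI	0.989	0.864	-0.011	0.872	1.122
CHI3L2	0.986	0.775	-0.014	0.896	1.086
CLIC1	0.972	0.836	-0.029	0.742	1.274
COL1A1	0.991	0.914	-0.009	0.842	1.166
COL1A2	0.846	0.024	-0.167	0.732	0.979
CXCR4	1.119	0.122	0.112	0.97	1.29
ECM2	0.982	0.769	-0.018	0.872	1.106
FCER1G	0.908	0.573	-0.096	0.65	1.268
FNDC3B	1.07	0.579	0.068	0.843	1.358
GPNMB	0.991	0.85	-0.009	0.901	1.09
HLA.DMA	0.705	0.002	-0.349	0.568	0.876
HMOX1	0.891	0.081	-0.115	0.783	1.014
IFI44	1.052	0.514	0.05	0.904	1.224
IGFBP2	1.1	0.073	0.095	0.991	1.22
IGFBP3	1.044	0.368	0.043	0.951	1.147
LY96	1.234	0.007	0.21	1.06	1.437
MMP2	0.988	0.863	-0.012	0.859	1.136
MTHFD2	0.892	0.245	-0.114	0.736	1.081
MYD88	1.108	0.417	0.103	0.865	1.42
NMI	1.122	0.305	0.115	0.9	1.398
PLSCR1	1.058	0.617	0.056	0.848	1.32
PTX3	0.98	0.705	-0.02	0.883	1.088
PXDN	0.981	0.775	-0.02	0.858	1.121
PYGL	0.874	0.101	-0.134	0.745	1.026
RBBP8	0.912	0.468	-0.093	0.71	1.171
SERPINE1	0.958	0.506	-0.043	0.845	1.087
SOD2	0.836	0.042	-0.179	0.704	0.994
SRPX	0.946	0.218	-0.056	0.865	1.034
TENT5A	1.214	0.015	0.194	1.039	1.418
TGFBI	0.98	0.791	-0.02	0.847	1.135
TIMP1	1.079	0.454	0.076	0.884	1.318
VSIG4	1.004	0.977	0.004	0.77	1.309
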