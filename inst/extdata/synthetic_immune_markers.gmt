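CD8_T_CELLS_SYNTH	synthetic marker set	GENE00001	GENE00002	GENE00003	GENE00004	GENE00005	GENE00006	GENE00007	GENE00008	GENE00009	GENE00010	GENE00011	GENE00012
CD4_T_CELLS_SYNTH	synthetic marker set	GENE00021	GENE00022	GENE00023	GENE00024	GENE00025	GENE00026	GENE00027	GENE00028	GENE00029	GENE00030	GENE00031	GENE00032
MACROPHAGES_SYNTH	synthetic marker set	GENE00041	GENE00042	GENE00043	GENE00044	GENE00045	GENE00046	GENE00047	GENE00048	GENE00049	GENE00050	GENE00051	GENE00052	GENE00053	GENE00054	GENE00055
DENDRITIC_CELLS_SYNTH	synthetic marker set	GENE00061	GENE00062	GENE00063	GENE00064	GENE00065	GENE00066	GENE00067	GENE00068	GENE00069	GENE00070	GENE00071	GENE00072
EXHAUSTED_T_SYNTH	synthetic marker set	GENE00081	GENE00082	GENE00083	GENE00084	GENE00085	GENE00086	GENE00087	GENE00088	GENE00089	GENE00090	GENE00091	GENE00092	GENE00093	GENE00094	GENE00095
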