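sample_id	fwd_barcode	rev_barcode	population
Tch001	BC01	BC01	Tchonka
Tch002	BC02	BC01	Tchonka
Tch003	BC03	BC01	Tchonka
Tch004	BC04	BC01	Tchonka
Tch005	BC05	BC01	Tchonka
Tch006	BC06	BC01	Tchonka
Tch007	BC07	BC01	Tchonka
Tch008	BC08	BC01	Tchonka
Tch009	BC09	BC01	Tchonka
Tch010	BC10	BC01	Tchonka
Tch011	BC01	BC02	Tchonka
Tch012	BC02	BC02	Tchonka
Tch013	BC03	BC02	Tchonka
Tch014	BC04	BC02	Tchonka
Tch015	BC05	BC02	Tchonka
Tch016	BC06	BC02	Tchonka
Tch017	BC07	BC02	Tchonka
Tch018	BC08	BC02	Tchonka
Tch019	BC09	BC02	Tchonka
Tch020	BC10	BC02	Tchonka
Tch021	BC01	BC03	Tchonka
Tch022	BC02	BC03	Tchonka
Tch023	BC03	BC03	Tchonka
Tch024	BC04	BC03	Tchonka
Tch025	BC05	BC03	Tchonka
Tch026	BC06	BC03	Tchonka
Tch027	BC07	BC03	Tchonka
Tch028	BC08	BC03	Tchonka
Tch029	BC09	BC03	Tchonka
Tch030	BC10	BC03	Tchonka
Tch031	BC01	BC04	Tchonka
Tch032	BC02	BC04	Tchonka
Tch033	BC03	BC04	Tchonka
Tch034	BC04	BC04	Tchonka
Tch035	BC05	BC04	Tchonka
Tch036	BC06	BC04	Tchonka
Tch037	BC07	BC04	Tchonka
Tch038	BC08	BC04	Tchonka
Tch039	BC09	BC04	Tchonka
Tch040	BC10	BC04	Tchonka
Tch041	BC01	BC05	Tchonka
Tch042	BC02	BC05	Tchonka
Tch043	BC03	BC05	Tchonka
Tch044	BC04	BC05	Tchonka
Tch045	BC05	BC05	Tchonka
Tch046	BC06	BC05	Tchonka
Tch047	BC07	BC05	Tchonka
Tch048	BC08	BC05	Tchonka
Tch049	BC09	BC05	Tchonka
Tch050	BC10	BC05	Tchonka
Tch051	BC01	BC06	Tchonka
Tch052	BC02	BC06	Tchonka
Tch053	BC03	BC06	Tchonka
Tch054	BC04	BC06	Tchonka
Tch055	BC05	BC06	Tchonka
Tch056	BC06	BC06	Tchonka
Tch057	BC07	BC06	Tchonka
Tch058	BC08	BC06	Tchonka
Tch059	BC09	BC06	Tchonka
Tch060	BC10	BC06	Tchonka
Tch061	BC01	BC07	Tchonka
Tch062	BC02	BC07	Tchonka
Tch063	BC03	BC07	Tchonka
Tch064	BC04	BC07	Tchonka
Tch065	BC05	BC07	Tchonka
Tch066	BC06	BC07	Tchonka
Tch067	BC07	BC07	Tchonka
Tch068	BC08	BC07	Tchonka
Tch069	BC09	BC07	Tchonka
Tch070	BC10	BC07	Tchonka
Tsh001	BC01	BC08	Tushunguti
Tsh002	BC02	BC08	Tushunguti
Tsh003	BC03	BC08	Tushunguti
Tsh004	BC04	BC08	Tushunguti
Tsh005	BC05	BC08	Tushunguti
Tsh006	BC06	BC08	Tushunguti
Tsh007	BC07	BC08	Tushunguti
Tsh008	BC08	BC08	Tushunguti
Tsh009	BC09	BC08	Tushunguti
Tsh010	BC10	BC08	Tushunguti
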