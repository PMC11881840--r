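sample_id	host_subject_id	host_age	diet	exposure	group
mouse01.wk10.0	mouse01	10	RC	Air	RC-Air
mouse01.wk12.0	mouse01	12	RC	Air	RC-Air
mouse01.wk14.0	mouse01	14	RC	Air	RC-Air
mouse01.wk16.0	mouse01	16	RC	Air	RC-Air
mouse01.wk18.0	mouse01	18	RC	Air	RC-Air
mouse01.wk19.5	mouse01	19.5	RC	Air	RC-Air
mouse02.wk10.0	mouse02	10	RC	Air	RC-Air
mouse02.wk12.0	mouse02	12	RC	Air	RC-Air
mouse02.wk14.0	mouse02	14	RC	Air	RC-Air
mouse02.wk16.0	mouse02	16	RC	Air	RC-Air
mouse02.wk18.0	mouse02	18	RC	Air	RC-Air
mouse02.wk19.5	mouse02	19.5	RC	Air	RC-Air
mouse03.wk10.0	mouse03	10	RC	Air	RC-Air
mouse03.wk12.0	mouse03	12	RC	Air	RC-Air
mouse03.wk14.0	mouse03	14	RC	Air	RC-Air
mouse03.wk16.0	mouse03	16	RC	Air	RC-Air
mouse03.wk18.0	mouse03	18	RC	Air	RC-Air
mouse03.wk19.5	mouse03	19.5	RC	Air	RC-Air
mouse04.wk10.0	mouse04	10	RC	Air	RC-Air
mouse04.wk12.0	mouse04	12	RC	Air	RC-Air
mouse04.wk14.0	mouse04	14	RC	Air	RC-Air
mouse04.wk16.0	mouse04	16	RC	Air	RC-Air
mouse04.wk18.0	mouse04	18	RC	Air	RC-Air
mouse04.wk19.5	mouse04	19.5	RC	Air	RC-Air
mouse05.wk10.0	mouse05	10	RC	Air	RC-Air
mouse05.wk12.0	mouse05	12	RC	Air	RC-Air
mouse05.wk14.0	mouse05	14	RC	Air	RC-Air
mouse05.wk16.0	mouse05	16	RC	Air	RC-Air
mouse05.wk18.0	mouse05	18	RC	Air	RC-Air
mouse05.wk19.5	mouse05	19.5	RC	Air	RC-Air
mouse06.wk10.0	mouse06	10	HFHC	Air	HFHC-Air
mouse06.wk12.0	mouse06	12	HFHC	Air	HFHC-Air
mouse06.wk14.0	mouse06	14	HFHC	Air	HFHC-Air
mouse06.wk16.0	mouse06	16	HFHC	Air	HFHC-Air
mouse06.wk18.0	mouse06	18	HFHC	Air	HFHC-Air
mouse06.wk19.5	mouse06	19.5	HFHC	Air	HFHC-Air
mouse07.wk10.0	mouse07	10	HFHC	Air	HFHC-Air
mouse07.wk12.0	mouse07	12	HFHC	Air	HFHC-Air
mouse07.wk14.0	mouse07	14	HFHC	Air	HFHC-Air
mouse07.wk16.0	mouse07	16	HFHC	Air	HFHC-Air
mouse07.wk18.0	mouse07	18	HFHC	Air	HFHC-Air
mouse07.wk19.5	mouse07	19.5	HFHC	Air	HFHC-Air
mouse08.wk10.0	mouse08	10	HFHC	Air	HFHC-Air
mouse08.wk12.0	mouse08	12	HFHC	Air	HFHC-Air
mouse08.wk14.0	mouse08	14	HFHC	Air	HFHC-Air
mouse08.wk16.0	mouse08	16	HFHC	Air	HFHC-Air
mouse08.wk18.0	mouse08	18	HFHC	Air	HFHC-Air
mouse08.wk19.5	mouse08	19.5	HFHC	Air	HFHC-Air
mouse09.wk10.0	mouse09	10	HFHC	Air	HFHC-Air
mouse09.wk12.0	mouse09	12	HFHC	Air	HFHC-Air
mouse09.wk14.0	mouse09	14	HFHC	Air	HFHC-Air
mouse09.wk16.0	mouse09	16	HFHC	Air	HFHC-Air
mouse09.wk18.0	mouse09	18	HFHC	Air	HFHC-Air
mouse09.wk19.5	mouse09	19.5	HFHC	Air	HFHC-Air
mouse10.wk10.0	mouse10	10	HFHC	Air	HFHC-Air
mouse10.wk12.0	mouse10	12	HFHC	Air	HFHC-Air
mouse10.wk14.0	mouse10	14	HFHC	Air	HFHC-Air
mouse10.wk16.0	mouse10	16	HFHC	Air	HFHC-Air
mouse10.wk18.0	mouse10	18	HFHC	Air	HFHC-Air
mouse10.wk19.5	mouse10	19.5	HFHC	Air	HFHC-Air
mouse11.wk10.0	mouse11	10	HFHC	IHC	HFHC-IHC
mouse11.wk12.0	mouse11	12	HFHC	IHC	HFHC-IHC
mouse11.wk14.0	mouse11	14	HFHC	IHC	HFHC-IHC
mouse11.wk16.0	mouse11	16	HFHC	IHC	HFHC-IHC
mouse11.wk18.0	mouse11	18	HFHC	IHC	HFHC-IHC
mouse11.wk19.5	mouse11	19.5	HFHC	IHC	HFHC-IHC
mouse12.wk10.0	mouse12	10	HFHC	IHC	HFHC-IHC
mouse12.wk12.0	mouse12	12	HFHC	IHC	HFHC-IHC
mouse12.wk14.0	mouse12	14	HFHC	IHC	HFHC-IHC
mouse12.wk16.0	mouse12	16	HFHC	IHC	HFHC-IHC
mouse12.wk18.0	mouse12	18	HFHC	IHC	HFHC-IHC
mouse12.wk19.5	mouse12	19.5	HFHC	IHC	HFHC-IHC
mouse13.wk10.0	mouse13	10	HFHC	IHC	HFHC-IHC
mouse13.wk12.0	mouse13	12	HFHC	IHC	HFHC-IHC
mouse13.wk14.0	mouse13	14	HFHC	IHC	HFHC-IHC
mouse13.wk16.0	mouse13	16	HFHC	IHC	HFHC-IHC
mouse13.wk18.0	mouse13	18	HFHC	IHC	HFHC-IHC
mouse13.wk19.5	mouse13	19.5	HFHC	IHC	HFHC-IHC
mouse14.wk10.0	mouse14	10	HFHC	IHC	HFHC-IHC
mouse14.wk12.0	mouse14	12	HFHC	IHC	HFHC-IHC
mouse14.wk14.0	mouse14	14	HFHC	IHC	HFHC-IHC
mouse14.wk16.0	mouse14	16	HFHC	IHC	HFHC-IHC
mouse14.wk18.0	mouse14	18	HFHC	IHC	HFHC-IHC
mouse14.wk19.5	mouse14	19.5	HFHC	IHC	HFHC-IHC
mouse15.wk10.0	mouse15	10	HFHC	IHC	HFHC-IHC
mouse15.wk12.0	mouse15	12	HFHC	IHC	HFHC-IHC
mouse15.wk14.0	mouse15	14	HFHC	IHC	HFHC-IHC
mouse15.wk16.0	mouse15	16	HFHC	IHC	HFHC-IHC
mouse15.wk18.0	mouse15	18	HFHC	IHC	HFHC-IHC
mouse15.wk19.5	mouse15	19.5	HFHC	IHC	HFHC-IHC
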