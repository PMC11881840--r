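feature_id	family
asv001	MuribaculaceaeLike
asv002	MuribaculaceaeLike
asv003	MuribaculaceaeLike
asv004	MuribaculaceaeLike
asv005	MuribaculaceaeLike
asv006	MuribaculaceaeLike
asv007	MuribaculaceaeLike
asv008	MuribaculaceaeLike
asv009	MuribaculaceaeLike
asv010	MuribaculaceaeLike
asv011	AkkermansiaceaeLike
asv012	AkkermansiaceaeLike
asv013	AkkermansiaceaeLike
asv014	AkkermansiaceaeLike
asv015	AkkermansiaceaeLike
asv016	AkkermansiaceaeLike
asv017	AkkermansiaceaeLike
asv018	AkkermansiaceaeLike
asv019	AkkermansiaceaeLike
asv020	AkkermansiaceaeLike
asv021	OtherFamily
asv022	OtherFamily
asv023	OtherFamily
asv024	OtherFamily
asv025	OtherFamily
asv026	OtherFamily
asv027	OtherFamily
asv028	OtherFamily
asv029	OtherFamily
asv030	OtherFamily
asv031	OtherFamily
asv032	OtherFamily
asv033	OtherFamily
asv034	OtherFamily
asv035	OtherFamily
asv036	OtherFamily
asv037	OtherFamily
asv038	OtherFamily
asv039	OtherFamily
asv040	OtherFamily
asv041	OtherFamily
asv042	OtherFamily
asv043	OtherFamily
asv044	OtherFamily
asv045	OtherFamily
asv046	OtherFamily
asv047	OtherFamily
asv048	OtherFamily
asv049	OtherFamily
asv050	OtherFamily
asv051	OtherFamily
asv052	OtherFamily
asv053	OtherFamily
asv054	OtherFamily
asv055	OtherFamily
asv056	OtherFamily
asv057	OtherFamily
asv058	OtherFamily
asv059	OtherFamily
asv060	OtherFamily
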