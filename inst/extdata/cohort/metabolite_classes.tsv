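feature_id	class
mtb001	rcAssoc
mtb002	rcAssoc
mtb003	rcAssoc
mtb004	rcAssoc
mtb005	rcAssoc
mtb006	rcAssoc
mtb007	rcAssoc
mtb008	rcAssoc
mtb009	rcAssoc
mtb010	rcAssoc
mtb011	rcAssoc
mtb012	rcAssoc
mtb013	hfhcIhcAssoc
mtb014	hfhcIhcAssoc
mtb015	hfhcIhcAssoc
mtb016	hfhcIhcAssoc
mtb017	hfhcIhcAssoc
mtb018	hfhcIhcAssoc
mtb019	hfhcIhcAssoc
mtb020	hfhcIhcAssoc
mtb021	hfhcIhcAssoc
mtb022	hfhcIhcAssoc
mtb023	hfhcIhcAssoc
mtb024	hfhcIhcAssoc
mtb025	none
mtb026	none
mtb027	none
mtb028	none
mtb029	none
mtb030	none
mtb031	none
mtb032	none
mtb033	none
mtb034	none
mtb035	none
mtb036	none
mtb037	none
mtb038	none
mtb039	none
mtb040	none
mtb041	none
mtb042	none
mtb043	none
mtb044	none
mtb045	none
mtb046	none
mtb047	none
mtb048	none
mtb049	none
mtb050	none
mtb051	none
mtb052	none
mtb053	none
mtb054	none
mtb055	none
mtb056	none
mtb057	none
mtb058	none
mtb059	none
mtb060	none
mtb061	none
mtb062	none
mtb063	none
mtb064	none
mtb065	none
mtb066	none
mtb067	none
mtb068	none
mtb069	none
mtb070	none
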