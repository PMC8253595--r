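#tag_id	feature_id	tail_length	terminal_U	sample_id
A001	featA	30	TRUE	toy
A002	featA	30	TRUE	toy
A003	featA	30	TRUE	toy
A004	featA	30	TRUE	toy
A005	featA	30	TRUE	toy
A006	featA	30	TRUE	toy
A007	featA	30	TRUE	toy
A008	featA	30	TRUE	toy
A009	featA	30	TRUE	toy
A010	featA	30	TRUE	toy
A011	featA	30	FALSE	toy
A012	featA	30	FALSE	toy
A013	featA	30	FALSE	toy
A014	featA	30	FALSE	toy
A015	featA	30	FALSE	toy
A016	featA	30	FALSE	toy
A017	featA	30	FALSE	toy
A018	featA	30	FALSE	toy
A019	featA	30	FALSE	toy
A020	featA	30	FALSE	toy
A021	featA	30	FALSE	toy
A022	featA	30	FALSE	toy
A023	featA	30	FALSE	toy
A024	featA	30	FALSE	toy
A025	featA	30	FALSE	toy
A026	featA	30	FALSE	toy
A027	featA	30	FALSE	toy
A028	featA	30	FALSE	toy
A029	featA	30	FALSE	toy
A030	featA	30	FALSE	toy
A031	featA	30	FALSE	toy
A032	featA	30	FALSE	toy
A033	featA	30	FALSE	toy
A034	featA	30	FALSE	toy
A035	featA	30	FALSE	toy
A036	featA	30	FALSE	toy
A037	featA	30	FALSE	toy
A038	featA	30	FALSE	toy
A039	featA	30	FALSE	toy
A040	featA	30	FALSE	toy
A041	featA	30	FALSE	toy
A042	featA	30	FALSE	toy
A043	featA	30	FALSE	toy
A044	featA	30	FALSE	toy
A045	featA	30	FALSE	toy
A046	featA	30	FALSE	toy
A047	featA	30	FALSE	toy
A048	featA	30	FALSE	toy
A049	featA	30	FALSE	toy
A050	featA	30	FALSE	toy
A051	featA	30	FALSE	toy
A052	featA	30	FALSE	toy
A053	featA	30	FALSE	toy
A054	featA	30	FALSE	toy
A055	featA	30	FALSE	toy
A056	featA	30	FALSE	toy
A057	featA	30	FALSE	toy
A058	featA	30	FALSE	toy
A059	featA	30	FALSE	toy
A060	featA	30	FALSE	toy
A061	featA	30	FALSE	toy
A062	featA	30	FALSE	toy
A063	featA	30	FALSE	toy
A064	featA	30	FALSE	toy
A065	featA	30	FALSE	toy
A066	featA	30	FALSE	toy
A067	featA	30	FALSE	toy
A068	featA	30	FALSE	toy
A069	featA	30	FALSE	toy
A070	featA	30	FALSE	toy
A071	featA	30	FALSE	toy
A072	featA	30	FALSE	toy
A073	featA	30	FALSE	toy
A074	featA	30	FALSE	toy
A075	featA	30	FALSE	toy
A076	featA	30	FALSE	toy
A077	featA	30	FALSE	toy
A078	featA	30	FALSE	toy
A079	featA	30	FALSE	toy
A080	featA	30	FALSE	toy
A081	featA	30	FALSE	toy
A082	featA	30	FALSE	toy
A083	featA	30	FALSE	toy
A084	featA	30	FALSE	toy
A085	featA	30	FALSE	toy
A086	featA	30	FALSE	toy
A087	featA	30	FALSE	toy
A088	featA	30	FALSE	toy
A089	featA	30	FALSE	toy
A090	featA	30	FALSE	toy
A091	featA	30	FALSE	toy
A092	featA	30	FALSE	toy
A093	featA	30	FALSE	toy
A094	featA	30	FALSE	toy
A095	featA	30	FALSE	toy
A096	featA	30	FALSE	toy
A097	featA	30	FALSE	toy
A098	featA	30	FALSE	toy
A099	featA	30	FALSE	toy
A100	featA	30	FALSE	toy
B001	featB	1	FALSE	toy
B002	featB	1	FALSE	toy
B003	featB	1	FALSE	toy
B004	featB	1	FALSE	toy
B005	featB	1	FALSE	toy
B006	featB	1	FALSE	toy
B007	featB	1	FALSE	toy
B008	featB	1	FALSE	toy
B009	featB	1	FALSE	toy
B010	featB	1	FALSE	toy
B011	featB	1	FALSE	toy
B012	featB	1	FALSE	toy
B013	featB	1	FALSE	toy
B014	featB	1	FALSE	toy
B015	featB	1	FALSE	toy
B016	featB	1	FALSE	toy
B017	featB	1	FALSE	toy
B018	featB	1	FALSE	toy
B019	featB	1	FALSE	toy
B020	featB	1	FALSE	toy
B021	featB	1	FALSE	toy
B022	featB	1	FALSE	toy
B023	featB	1	FALSE	toy
B024	featB	1	FALSE	toy
B025	featB	1	FALSE	toy
B026	featB	1	FALSE	toy
B027	featB	1	FALSE	toy
B028	featB	1	FALSE	toy
B029	featB	1	FALSE	toy
B030	featB	1	FALSE	toy
B031	featB	1	FALSE	toy
B032	featB	1	FALSE	toy
B033	featB	1	FALSE	toy
B034	featB	1	FALSE	toy
B035	featB	1	FALSE	toy
B036	featB	1	FALSE	toy
B037	featB	1	FALSE	toy
B038	featB	1	FALSE	toy
B039	featB	1	FALSE	toy
B040	featB	1	FALSE	toy
B041	featB	1	FALSE	toy
B042	featB	1	FALSE	toy
B043	featB	1	FALSE	toy
B044	featB	1	FALSE	toy
B045	featB	1	FALSE	toy
B046	featB	1	FALSE	toy
B047	featB	1	FALSE	toy
B048	featB	1	FALSE	toy
B049	featB	1	FALSE	toy
B050	featB	1	FALSE	toy
B051	featB	1	FALSE	toy
B052	featB	1	FALSE	toy
B053	featB	1	FALSE	toy
B054	featB	1	FALSE	toy
B055	featB	1	FALSE	toy
B056	featB	1	FALSE	toy
B057	featB	1	FALSE	toy
B058	featB	1	FALSE	toy
B059	featB	1	FALSE	toy
B060	featB	1	FALSE	toy
B061	featB	1	FALSE	toy
B062	featB	1	FALSE	toy
B063	featB	1	FALSE	toy
B064	featB	1	FALSE	toy
B065	featB	1	FALSE	toy
B066	featB	1	FALSE	toy
B067	featB	1	FALSE	toy
B068	featB	1	FALSE	toy
B069	featB	1	FALSE	toy
B070	featB	1	FALSE	toy
B071	featB	1	FALSE	toy
B072	featB	1	FALSE	toy
B073	featB	1	FALSE	toy
B074	featB	1	FALSE	toy
B075	featB	1	FALSE	toy
B076	featB	1	FALSE	toy
B077	featB	1	FALSE	toy
B078	featB	1	FALSE	toy
B079	featB	1	FALSE	toy
B080	featB	1	FALSE	toy
B081	featB	1	FALSE	toy
B082	featB	1	FALSE	toy
B083	featB	1	FALSE	toy
B084	featB	1	FALSE	toy
B085	featB	1	FALSE	toy
B086	featB	1	FALSE	toy
B087	featB	1	FALSE	toy
B088	featB	1	FALSE	toy
B089	featB	1	FALSE	toy
B090	featB	1	FALSE	toy
B091	featB	1	FALSE	toy
B092	featB	1	FALSE	toy
B093	featB	1	FALSE	toy
B094	featB	1	FALSE	toy
B095	featB	1	FALSE	toy
B096	featB	1	FALSE	toy
B097	featB	1	FALSE	toy
B098	featB	1	FALSE	toy
B099	featB	1	FALSE	toy
C001	featC	0	FALSE	toy
C002	featC	2	TRUE	toy
C003	featC	5	FALSE	toy
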