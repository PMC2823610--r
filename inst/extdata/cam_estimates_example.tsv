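id	haplogroup	sam_site	sam_region	cam_lat	cam_lon	cam_region
LWC001	1b	MTCM	North	5.69426	10.98525	North
LWC002	1b	MTCM	North	4.79855	9.2901	North
LWC003	1b	MTCM	North	5.88904	10.14165	North
LWC004	1b	GGNP	North	6.06406	10.804	North
LWC005	1b	MSSE	North	6.01814	9.33696	North
LWC006	1b	MTCM	North	6.16266	9.770035	North
LWC007	1b	GGNP	North	6.4109	10.4424	North
LWC008	1b	MTCM	North	5.508405	10.144	North
LWC009	1b	MSSE	North	6.02645	10.4546	North
LWC010	1b	GGNP	North	6.686045	11.5976	North
LWC011	1b	MTCM	North	4.999935	9.59359	North
LWC012	1b	GGNP	North	6.387525	10.6643	North
LWC014	1b	GGNP	North	6.171715	11.5504	North
LWC017	1b	GGNP	North	6.20374	11.4116	North
LWC018	1b	MTCM	North	5.71996	9.154565	North
LWC019	1b	GGNP	North	6.819025	10.63615	North
LWC021	1b	GGNP	North	6.78872	11.53365	North
LWC023	1b	MSSE	North	5.784825	10.3854	North
LWC024	1b	MTCM	North	4.15989	9.14837	North
LWC026	1b	MSSE	North	5.74762	10.60665	North
LWC028	1b	MTCM	North	4.3105	9.169405	North
LWC030	1b	MTCM	North	5.691485	10.45	North
LWC033	1b	MTCM	North	5.88719	9.870615	North
LWC034	1b	AKZN	North	6.09503	11.2155	North
LWC036	1b	MTCM	North	5.709555	10.8607	North
LWC038	1b	MSSE	North	5.240895	10.1503	North
LWC041	1b	MTCM	North	5.97631	9.97306	North
LWC043	1b	GGNP	North	6.637165	10.9659	North
LWC044	1b	MTCM	North	6.04163	9.87016	North
LWC045	1b	MTCM	North	5.55618	9.42	North
LWC046	1b	MTCM	North	5.767895	10.37835	North
LWC016	1b	MANB	North	5.616985	11.6057	Transition
LWC027	2a	DJBR	South	3.47309	12.80025	South
LWC031	2a	DJBR	South	3.933035	13.092	South
LWC032	2a	CMNP	South	3.65541	11.2014	South
LWC040	2a	MANB	North	5.366435	11.657	Transition
LWC015	2b	CRNP	North	5.947675	11.5971	Transition
LWC025	2c	DJBR	South	5.077715	11.7409	Transition
LWC013	2c	CMNP	South	3.578515	12.5198	South
LWC020	2c	CMNP	South	3.364205	12.05345	South
LWC022	2c	DJBR	South	3.3743	12.344	South
LWC029	2c	DJBR	South	4.137805	12.88305	South
LWC035	2c	DJBR	South	4.54397	12.2347	South
LWC037	2c	CMNP	South	4.33148	11.3812	South
LWC042	2c	DJBR	South	3.38591	12.71325	South
LWC039	2c	MSSE	North	4.7324	10.4764	North
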