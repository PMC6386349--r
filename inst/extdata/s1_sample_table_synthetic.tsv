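sample_id	country	preservation	best_match_12s	evalue_12s	pident_12s	best_match_16s	evalue_16s	pident_16s
L001	Bangladesh	RNAlater	Tupaia belangeri	6e-49	93.6	Tupaia belangeri	7e-96	94
L002	Bangladesh	RNAlater	Macaca fascicularis	3e-70	93.2			
L003	Bangladesh	RNAlater	Muntiacus muntjak	8e-33	98.7	Muntiacus muntjak	3e-25	90.5
L004	Bangladesh	RNAlater	Macaca fascicularis	1e-73	95			
L005	Bangladesh	RNAlater	Macaca mulatta	6e-75	92.1			
L006	Bangladesh	RNAlater	Muntiacus muntjak	7e-24	96	Muntiacus muntjak	1e-27	98.1
L007	Bangladesh	RNAlater	Muntiacus muntjak	4e-97	95.6			
L008	Bangladesh	RNAlater	Herpestes javanicus	9e-80	93.8			
L009	Bangladesh	RNAlater	Macaca fascicularis	8e-114	99.2			
L010	Bangladesh	RNAlater	Muntiacus muntjak	6e-62	97.3	Muntiacus muntjak	2e-98	94
L011	Bangladesh	RNAlater	Muntiacus muntjak	8e-28	96.1	Muntiacus muntjak	1e-74	93.9
L012	Bangladesh	RNAlater	Herpestes javanicus	6e-57	96			
L013	Bangladesh	RNAlater	Muntiacus muntjak	9e-71	96.1			
L014	Bangladesh	RNAlater	Homo sapiens	5e-34	98.1			
L015	Bangladesh	RNAlater	Gallus gallus	3e-64	96.2			
L016	Bangladesh	RNAlater	Sus scrofa	5e-24	97.6			
L017	Bangladesh	RNAlater	Homo sapiens	8e-78	96.3			
L018	Bangladesh	RNAlater	Macaca mulatta	2e-14	87.4			
L019	Cambodia	RNAlater	Paradoxurus hermaphroditus	3e-57	98.4			
L020	Cambodia	RNAlater	Tragulus kanchil	1e-52	97.3			
L021	Cambodia	RNAlater	Fejervarya multistriata	9e-42	98.1			
L022	Cambodia	RNAlater	Paradoxurus hermaphroditus	6e-96	99.1	Paradoxurus hermaphroditus	3e-78	91.9
L023	Cambodia	RNAlater	Hipposideros bicolor	8e-52	98.5			
L024	Cambodia	95% ethanol	Fejervarya multistriata	4e-67	98.3	Fejervarya multistriata	1e-81	96.1
L025	Cambodia	RNAlater	Macaca fascicularis	5e-57	92.7			
L026	Cambodia	RNAlater	Rusa unicolor	4e-104	97.2	Rusa unicolor	3e-31	96.1
L027	Cambodia	RNAlater	Menetes berdmorei	7e-51	93.1	Menetes berdmorei	5e-38	91.2
L028	Cambodia	95% ethanol	Viverra zibetha	1e-40	98.5			
L029	Cambodia	RNAlater	Paradoxurus hermaphroditus	3e-45	93.8	Paradoxurus hermaphroditus	9e-95	95.7
L030	Cambodia	RNAlater	Tragulus kanchil	9e-93	99.2	Tragulus kanchil	2e-96	93.2
L031	Cambodia	95% ethanol	Rusa unicolor	6e-106	94.2			
L032	Cambodia	95% ethanol	Viverra zibetha	3e-52	98	Viverra zibetha	9e-113	90.8
L033	Cambodia	RNAlater	Tragulus kanchil	2e-33	98.1			
L034	Cambodia	95% ethanol	Paradoxurus hermaphroditus	8e-111	93.5			
L035	Cambodia	RNAlater	Tragulus kanchil	5e-35	94.2			
L036	Cambodia	RNAlater	Hipposideros bicolor	9e-107	93.6	Hipposideros bicolor	2e-119	94
L037	Cambodia	RNAlater	Paradoxurus hermaphroditus	3e-56	99.9			
L038	Cambodia	RNAlater	Paradoxurus hermaphroditus	7e-114	94			
L039	Cambodia	95% ethanol	Rusa unicolor	6e-101	97.7	Rusa unicolor	3e-89	91.7
L040	Cambodia	RNAlater	Fejervarya multistriata	8e-89	95	Fejervarya multistriata	1e-66	96.6
L041	Cambodia	RNAlater	Paradoxurus hermaphroditus	9e-32	98			
L042	Cambodia	RNAlater	Bos taurus	9e-102	98.9			
L043	Cambodia	RNAlater	Rattus rattus	7e-29	98.8			
L044	Cambodia	RNAlater	Homo sapiens	9e-108	99			
L045	Cambodia	RNAlater	Bos taurus	8e-36	99.2			
L046	Cambodia	RNAlater	Hipposideros bicolor	2e-14	87.8			
L047	China	RNAlater	Lophura nycthemera	2e-58	93.4	Lophura nycthemera	9e-103	95.3
L048	China	RNAlater	Rusa unicolor	8e-114	93.9			
L049	China	RNAlater	Paradoxurus hermaphroditus	3e-40	94.2	Paradoxurus hermaphroditus	1e-112	96.5
L050	China	RNAlater	Rusa unicolor	9e-68	93.7			
L051	China	RNAlater	Muntiacus muntjak	4e-111	98.2	Muntiacus muntjak	9e-34	95.8
L052	China	RNAlater	Muntiacus muntjak	8e-28	92	Muntiacus muntjak	8e-108	96.7
L053	China	RNAlater	Niviventer excelsior	1e-61	98.8			
L054	China	RNAlater	Paradoxurus hermaphroditus	8e-39	94.5	Paradoxurus hermaphroditus	6e-70	94.6
L055	China	RNAlater	Lophura nycthemera	5e-46	94			
L056	China	RNAlater	Lophura nycthemera	4e-40	93.4			
L057	China	RNAlater	Lophura nycthemera	1e-112	99.4	Lophura nycthemera	6e-24	92.5
L058	China	RNAlater	Muntiacus muntjak	4e-67	95.5			
L059	China	RNAlater	Sus scrofa	5e-92	97.4			
L060	China	RNAlater	Homo sapiens	5e-106	99.7			
L061	China	RNAlater	Homo sapiens	2e-43	98.5			
L062	China	RNAlater	Homo sapiens	3e-85	96.6			
L063	China	RNAlater	Paradoxurus hermaphroditus	2e-14	85.4			
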