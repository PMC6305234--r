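protein_id	signal_start	H	C	order_indicator	prob	label	beta_intercept	beta_H	beta_C	beta_order	signal_case
SYN0001	45	3	1	1	0.268941421369995	secretory	-2.5	0.25	-0.75	1.5	6
SYN0002	106	2.9	0	1	0.431680016521752	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0003	10	-8	-3	0	0.0953494648991095	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0004	38	-5.4	0	1	0.0870657724402712	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0005	80	-4.6	0	1	0.104331223119001	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0006	70	-11.3	1	1	0.0102011629407696	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0007	90	-5.4	-1	1	0.167981614866076	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0008	82	0.5	-1	1	0.468790626626244	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0009	94	4.3	0	1	0.518741215878535	secretory	-2.5	0.25	-0.75	1.5	6
SYN0010	66	7.4	0	1	0.700567142473973	secretory	-2.5	0.25	-0.75	1.5	6
SYN0011	18	3.4	-1	1	0.645656306225795	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0012	74	-8.9	0	1	0.0382356917659582	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0013	84	-2.8	-1	1	0.278884821977137	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0014	50	-1.1	-2	1	0.55601389054462	secretory	-2.5	0.25	-0.75	1.5	6
SYN0015	64	-9.8	-1	1	0.0629733560569965	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0016	31	-3.5	-1	1	0.245085013132372	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0017	83	-0.3	-1	1	0.41945769517934	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0018	63	-16	-3	1	0.0600866501740076	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0019	25	-5.1	-1	0	0.0463091498485004	non_secretory	-2.5	0.25	-0.75	1.5	6
SYN0020	53	-5.8	-1	0	0.0391657227967644	non_secretory	-2.5	0.25	-0.75	1.5	6
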