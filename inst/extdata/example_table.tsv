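id	label	group
SYN0001	secretory	groupA
SYN0002	non_secretory	groupA
SYN0003	non_secretory	groupA
SYN0004	non_secretory	groupA
SYN0005	non_secretory	groupA
SYN0006	non_secretory	groupA
SYN0007	non_secretory	groupA
SYN0008	non_secretory	groupA
SYN0009	secretory	groupA
SYN0010	secretory	groupA
SYN0011	non_secretory	groupB
SYN0012	non_secretory	groupB
SYN0013	non_secretory	groupB
SYN0014	secretory	groupB
SYN0015	non_secretory	groupB
SYN0016	non_secretory	groupB
SYN0017	non_secretory	groupB
SYN0018	non_secretory	groupB
SYN0019	non_secretory	groupB
SYN0020	non_secretory	groupB
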