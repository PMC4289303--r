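# Functional TRA/TRD gene-segment repertoire sizes (bovine from the UMD3.1
# annotation; human and murine reference repertoires). v_subgroups counts
# subgroups with at least one functional member. traj_total is the total
# annotated TRAJ gene count.
species	v_functional	v_subgroups	traj_functional	traj_total	trdd_functional	trdj_functional
bovine	215	38	52	62	5	3
human	48	37	50	61	3	4
murine	87	23	38	60	2	2
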