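type	key1	key2	value
param	duplex_init	-	4.09
param	au_end	-	0.45
param	loop_base	-	1.7
param	loop_per_nt	-	0.35
param	max_loop	-	30
param	ss_pair_penalty	-	1
param	temperature_c	-	37
stack	AU	AU	-0.93
stack	AU	UA	-1.1
stack	AU	CG	-2.24
stack	AU	GC	-2.08
stack	AU	GU	-0.55
stack	AU	UG	-1.36
stack	UA	AU	-1.33
stack	UA	UA	-0.93
stack	UA	CG	-2.35
stack	UA	GC	-2.11
stack	UA	GU	-1.27
stack	UA	UG	-1
stack	CG	AU	-2.11
stack	CG	UA	-2.08
stack	CG	CG	-3.26
stack	CG	GC	-2.36
stack	CG	GU	-1.41
stack	CG	UG	-2.11
stack	GC	AU	-2.35
stack	GC	UA	-2.24
stack	GC	CG	-3.42
stack	GC	GC	-3.26
stack	GC	GU	-1.53
stack	GC	UG	-2.51
stack	GU	AU	-1
stack	GU	UA	-1.36
stack	GU	CG	-2.51
stack	GU	GC	-2.11
stack	GU	GU	0.47
stack	GU	UG	-0.5
stack	UG	AU	-1.27
stack	UG	UA	-0.55
stack	UG	CG	-1.53
stack	UG	GC	-1.41
stack	UG	GU	0.3
stack	UG	UG	0.47
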