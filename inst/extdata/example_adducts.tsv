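adduct_id	precursor_mz	product_mz	rt	formula	delta_ppm_reported	rdb_reported	direction
H483	529.2973	413.2512	10.6	C22H44O12N2	1.1	2.0	down
H187	406.2178	290.1712	11.5	C17H31O8N3	-1.4	4.0	down
L114	258.0947	142.0477	3.30	NA	NA	NA	up
L127	266.0822	150.0357	8.20	NA	NA	NA	up
H342	459.2450	343.1968	10.3	C20H34O8N4	0.1	6.0	down
L129	266.1242	150.0776	9.90	C11H14O3N5	-2.1	7.5	up
H403	482.2248	366.1769	4.50	C21H31O8N5	0.5	9.0	down
H368	466.2640	350.2189	14.0	C20H33O5N8	-1.4	8.5	down
L189	291.0887	175.0419	7.80	NA	NA	NA	up
H264	430.1841	314.1348	10.2	C18H27O9N3	4.8	6.5	up
H204	411.2129	295.1653	17.1	C20H31O7N2	0.7	6.0	down
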