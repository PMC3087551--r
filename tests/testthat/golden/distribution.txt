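genome	lpxA	lpxC	lpxD	lpxH	lpxB	lpxK	waaA	lpxL	lpxM	fabZ
G09	1	2	1	2	2	.	2	.	1	2
G11	1	1	1	1	2	1	1	.	1	2
G15	1	1	1	2	4	1	1	.	1	2
G01	1	.	1	2	2	2	1	.	1	3
G06	1	1	1	2	2	1	1	.	1	2
G12	.	1	1	2	2	2	1	.	.	3
G18	1	1	1	2	2	2	2	.	.	3
G20	1	1	2	3	2	2	2	.	1	3
G03	1	1	1	2	.	1	2	.	2	2
G02	1	1	1	2	1	1	.	1	1	1
G19	1	2	1	1	1	1	.	1	1	1
G17	2	1	1	2	1	1	.	1	1	2
G10	1	1	1	2	1	1	1	1	2	2
G14	.	1	1	1	2	1	.	.	1	1
G08	.	2	1	1	2	2	.	.	1	1
G04	.	1	1	1	2	.	.	.	1	3
G07	.	1	1	1	2	.	.	.	1	3
G13	1	2	1	.	1	1	.	1	1	1
G16	1	1	1	.	1	1	1	1	1	1
G05	1	1	1	1	1	1	1	1	1	1
# gain lpxA -> N21
# loss lpxA -> G12
# loss lpxA -> N25
# duplication lpxA -> N21
# duplication lpxA -> N31
# gain lpxC -> N21
# loss lpxC -> G01
# duplication lpxC -> N21
# duplication lpxC -> N25
# duplication lpxC -> N36
# duplication lpxC -> N38
# duplication lpxC -> N30
# duplication lpxC -> N34
# gain lpxD -> N21
# duplication lpxD -> N28
# duplication lpxD -> N24
# gain lpxH -> N21
# loss lpxH -> N38
# duplication lpxH -> N21
# duplication lpxH -> N30
# duplication lpxH -> N22
# duplication lpxH -> G09
# duplication lpxH -> G20
# duplication lpxH -> N30
# gain lpxB -> N21
# loss lpxB -> G03
# duplication lpxB -> N21
# duplication lpxB -> N24
# duplication lpxB -> N24
# duplication lpxB -> N28
# duplication lpxB -> N28
# duplication lpxB -> N28
# duplication lpxB -> N35
# duplication lpxB -> G15
# duplication lpxB -> N25
# duplication lpxB -> N30
# gain lpxK -> N21
# loss lpxK -> G09
# loss lpxK -> N39
# duplication lpxK -> N28
# duplication lpxK -> N26
# duplication lpxK -> G01
# gain waaA -> N21
# loss waaA -> N31
# loss waaA -> N25
# loss waaA -> G13
# duplication waaA -> N21
# duplication waaA -> N36
# gain lpxL -> N21
# loss lpxL -> N23
# loss lpxL -> N25
# gain lpxM -> N21
# loss lpxM -> N37
# duplication lpxM -> N30
# duplication lpxM -> N23
# gain fabZ -> N21
# duplication fabZ -> N21
# duplication fabZ -> N32
# duplication fabZ -> N35
# duplication fabZ -> N21
# duplication fabZ -> N28
# duplication fabZ -> N33
# duplication fabZ -> N39
# duplication fabZ -> N39
# duplication fabZ -> N39
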