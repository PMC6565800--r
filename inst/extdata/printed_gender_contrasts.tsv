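muscle	parameter	direction	percent	p_band
biceps	z	increase	54	<0.001
biceps	r	increase	56	<0.001
biceps	fc	increase	37	<0.001
biceps	pa	decrease	44	<0.001
biceps	ri	increase	164	<0.001
biceps	re	increase	36	<0.001
biceps	xc	decrease	13	<0.05
biceps	mc	decrease	63	<0.001
triceps	z	increase	50	<0.001
triceps	r	increase	51	<0.001
triceps	fc	NS	NA	NS
triceps	pa	decrease	46	<0.001
triceps	ri	increase	121	<0.001
triceps	re	increase	48	<0.01
triceps	xc	decrease	18	<0.05
triceps	mc	decrease	27	NS
abductor_pollicis_brevis	z	NS	NA	NS
abductor_pollicis_brevis	r	NS	NA	NS
abductor_pollicis_brevis	fc	increase	30	<0.001
abductor_pollicis_brevis	pa	decrease	17	<0.001
abductor_pollicis_brevis	ri	NS	NA	NS
abductor_pollicis_brevis	re	NS	NA	NS
abductor_pollicis_brevis	xc	NS	NA	NS
abductor_pollicis_brevis	mc	decrease	35	<0.001
trapezius	z	increase	15	<0.01
trapezius	r	increase	16	<0.001
trapezius	fc	increase	40	<0.001
trapezius	pa	decrease	16	<0.05
trapezius	ri	increase	33	<0.05
trapezius	re	increase	8	<0.05
trapezius	xc	NS	NA	NS
trapezius	mc	decrease	27	<0.001
rectus_femoris	z	increase	69	<0.001
rectus_femoris	r	increase	71	<0.001
rectus_femoris	fc	increase	62	<0.001
rectus_femoris	pa	decrease	52	<0.001
rectus_femoris	ri	increase	190	<0.001
rectus_femoris	re	increase	50	<0.001
rectus_femoris	xc	decrease	14	<0.01
rectus_femoris	mc	decrease	45	<0.05
vastus_lateralis	z	increase	80	<0.001
vastus_lateralis	r	increase	85	<0.001
vastus_lateralis	fc	increase	17	<0.01
vastus_lateralis	pa	decrease	63	<0.001
vastus_lateralis	ri	increase	311	<0.001
vastus_lateralis	re	increase	48	<0.001
vastus_lateralis	xc	decrease	32	<0.001
vastus_lateralis	mc	decrease	69	<0.001
gastrocnemius	z	increase	49	<0.001
gastrocnemius	r	increase	52	<0.001
gastrocnemius	fc	increase	26	<0.01
gastrocnemius	pa	decrease	47	<0.001
gastrocnemius	ri	increase	197	<0.001
gastrocnemius	re	increase	36	<0.001
gastrocnemius	xc	decrease	22	<0.001
gastrocnemius	mc	decrease	46	<0.01
tibialis_anterior	z	increase	53	<0.001
tibialis_anterior	r	increase	57	<0.001
tibialis_anterior	fc	increase	23	<0.01
tibialis_anterior	pa	decrease	43	<0.001
tibialis_anterior	ri	increase	204	<0.001
tibialis_anterior	re	increase	36	<0.001
tibialis_anterior	xc	decrease	16	<0.01
tibialis_anterior	mc	decrease	46	<0.001
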