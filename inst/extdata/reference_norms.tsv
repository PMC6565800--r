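muscle	gender	parameter	mean	sd	n	unit
biceps	men	z	86.4	19.2	25	ohm
biceps	men	r	84.2	20.2	25	ohm
biceps	men	fc	42.3	6.4	25	kHz
biceps	men	pa	13.1	5.1	25	deg
biceps	men	ri	140.8	84.6	25	ohm
biceps	men	re	114.0	19.2	25	ohm
biceps	men	xc	18.1	3.7	25	ohm
biceps	men	mc	17.5	7.6	25	pF
biceps	women	z	133.0	27.6	25	ohm
biceps	women	r	131.9	28.1	25	ohm
biceps	women	fc	58.1	8.0	25	kHz
biceps	women	pa	7.3	3.1	25	deg
biceps	women	ri	372.4	211.7	25	ohm
biceps	women	re	154.9	26.9	25	ohm
biceps	women	xc	15.7	4.3	25	ohm
biceps	women	mc	6.4	3.0	25	pF
triceps	men	z	102.8	19.4	25	ohm
triceps	men	r	101.4	20.1	25	ohm
triceps	men	fc	30.9	6.3	25	kHz
triceps	men	pa	9.1	3.9	25	deg
triceps	men	ri	258.9	123.0	25	ohm
triceps	men	re	131.8	18.5	25	ohm
triceps	men	xc	15.2	4.1	25	ohm
triceps	men	mc	15.5	6.6	25	pF
triceps	women	z	154.1	31.2	25	ohm
triceps	women	r	153.5	31.4	25	ohm
triceps	women	fc	63.3	95.4	25	kHz
triceps	women	pa	4.8	2.1	25	deg
triceps	women	ri	573.4	288.4	25	ohm
triceps	women	re	195.9	116.0	25	ohm
triceps	women	xc	12.5	4.1	25	ohm
triceps	women	mc	11.3	28.6	25	pF
abductor_pollicis_brevis	men	z	42.8	6.4	25	ohm
abductor_pollicis_brevis	men	r	42.2	6.2	25	ohm
abductor_pollicis_brevis	men	fc	73.5	14.1	25	kHz
abductor_pollicis_brevis	men	pa	8.8	1.9	25	deg
abductor_pollicis_brevis	men	ri	78.6	20.7	25	ohm
abductor_pollicis_brevis	men	re	50.6	9.1	25	ohm
abductor_pollicis_brevis	men	xc	6.6	2.0	25	ohm
abductor_pollicis_brevis	men	mc	17.8	4.0	25	pF
abductor_pollicis_brevis	women	z	52.2	25.8	25	ohm
abductor_pollicis_brevis	women	r	51.7	25.8	25	ohm
abductor_pollicis_brevis	women	fc	95.9	19.8	25	kHz
abductor_pollicis_brevis	women	pa	7.3	1.9	25	deg
abductor_pollicis_brevis	women	ri	133.9	214.7	25	ohm
abductor_pollicis_brevis	women	re	59.2	27.1	25	ohm
abductor_pollicis_brevis	women	xc	6.3	1.9	25	ohm
abductor_pollicis_brevis	women	mc	11.6	3.7	25	pF
trapezius	men	z	71.7	15.4	25	ohm
trapezius	men	r	70.4	15.9	25	ohm
trapezius	men	fc	45.1	7.2	25	kHz
trapezius	men	pa	10.6	4.6	25	deg
trapezius	men	ri	144.5	90.9	25	ohm
trapezius	men	re	90.8	15.1	25	ohm
trapezius	men	xc	12.3	3.6	25	ohm
trapezius	men	mc	18.2	8.5	25	pF
trapezius	women	z	82.7	17.4	25	ohm
trapezius	women	r	81.7	17.8	25	ohm
trapezius	women	fc	63.2	18.9	25	kHz
trapezius	women	pa	8.9	3.7	25	deg
trapezius	women	ri	193.0	148.0	25	ohm
trapezius	women	re	98.5	17.7	25	ohm
trapezius	women	xc	12.0	3.7	25	ohm
trapezius	women	mc	13.3	12.1	25	pF
rectus_femoris	men	z	83.1	16.1	25	ohm
rectus_femoris	men	r	81.7	16.6	25	ohm
rectus_femoris	men	fc	33.2	4.2	25	kHz
rectus_femoris	men	pa	10.5	3.5	25	deg
rectus_femoris	men	ri	173.9	73.5	25	ohm
rectus_femoris	men	re	108.5	17.0	25	ohm
rectus_femoris	men	xc	14.4	2.5	25	ohm
rectus_femoris	men	mc	18.8	6.0	25	pF
rectus_femoris	women	z	140.9	19.2	25	ohm
rectus_femoris	women	r	140.4	19.1	25	ohm
rectus_femoris	women	fc	53.7	69.3	25	kHz
rectus_femoris	women	pa	5.0	1.2	25	deg
rectus_femoris	women	ri	505.1	164.2	25	ohm
rectus_femoris	women	re	163.3	23.9	25	ohm
rectus_femoris	women	xc	12.3	3.4	25	ohm
rectus_femoris	women	mc	10.2	19.7	25	pF
vastus_lateralis	men	z	68.9	15.9	25	ohm
vastus_lateralis	men	r	66.6	16.4	25	ohm
vastus_lateralis	men	fc	31.8	4.2	25	kHz
vastus_lateralis	men	pa	15.1	4.4	25	deg
vastus_lateralis	men	ri	106.1	65.7	25	ohm
vastus_lateralis	men	re	98.2	18.3	25	ohm
vastus_lateralis	men	xc	17.1	3.4	25	ohm
vastus_lateralis	men	mc	27.4	7.8	25	pF
vastus_lateralis	women	z	124.0	23.0	25	ohm
vastus_lateralis	women	r	123.4	23.0	25	ohm
vastus_lateralis	women	fc	37.3	8.4	25	kHz
vastus_lateralis	women	pa	5.5	2.0	25	deg
vastus_lateralis	women	ri	436.7	155.6	25	ohm
vastus_lateralis	women	re	146.0	27.2	25	ohm
vastus_lateralis	women	xc	11.6	3.9	25	ohm
vastus_lateralis	women	mc	8.4	3.6	25	pF
gastrocnemius	men	z	68.2	13.4	25	ohm
gastrocnemius	men	r	66.6	13.3	25	ohm
gastrocnemius	men	fc	52.5	7.9	25	kHz
gastrocnemius	men	pa	12.2	2.8	25	deg
gastrocnemius	men	ri	100.3	38.1	25	ohm
gastrocnemius	men	re	85.6	16.9	25	ohm
gastrocnemius	men	xc	14.2	3.8	25	ohm
gastrocnemius	men	mc	17.7	4.8	25	pF
gastrocnemius	women	z	102.1	20.6	25	ohm
gastrocnemius	women	r	101.5	20.6	25	ohm
gastrocnemius	women	fc	66.5	20.3	25	kHz
gastrocnemius	women	pa	6.4	1.7	25	deg
gastrocnemius	women	ri	298.5	116.7	25	ohm
gastrocnemius	women	re	116.6	22.4	25	ohm
gastrocnemius	women	xc	11.1	2.8	25	ohm
gastrocnemius	women	mc	9.5	13.9	25	pF
tibialis_anterior	men	z	59.3	8.0	25	ohm
tibialis_anterior	men	r	57.5	7.8	25	ohm
tibialis_anterior	men	fc	48.4	5.2	25	kHz
tibialis_anterior	men	pa	14.0	1.8	25	deg
tibialis_anterior	men	ri	72.8	18.4	25	ohm
tibialis_anterior	men	re	78.6	10.6	25	ohm
tibialis_anterior	men	xc	14.3	2.4	25	ohm
tibialis_anterior	men	mc	22.6	4.5	25	pF
tibialis_anterior	women	z	91.1	20.5	25	ohm
tibialis_anterior	women	r	90.2	20.6	25	ohm
tibialis_anterior	women	fc	59.7	16.3	25	kHz
tibialis_anterior	women	pa	7.9	2.5	25	deg
tibialis_anterior	women	ri	221.7	105.7	25	ohm
tibialis_anterior	women	re	107.4	22.3	25	ohm
tibialis_anterior	women	xc	12.1	2.8	25	ohm
tibialis_anterior	women	mc	12.2	12.8	25	pF
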