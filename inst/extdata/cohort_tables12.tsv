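subject_id	cgvhd	relapse	batch	donor_source	hla_match	ptcy	all_risk	agvhd	conditioning	prophylaxis	sampling_day
UPN01	1	0	C1	unrelated	10/10	0	high	1	Flu/Tre/Thiotepa	Tacro/MMF	100
UPN02	1	1	C1	related	5/10	1	high	1	TBI/Cy	Tacro/MMF/PTCy	100
UPN03	0	1	C1	related	5/10	1	high	1	Flu/TBI/Cy	Tacro/MMF/PTCy	100
UPN04	0	1	C1	related	9/10	0	high	1	Thiotepa/TBI/Cy	Tacro/MMF	100
UPN05	0	0	C1	related	10/10	0	high	1	Etoposide/TBI/Cy	CsA/MMF	100
UPN06	0	1	C2	related	10/10	0	standard	0	TBI/Cy	Tacro/MMF	100
UPN07	1	0	C2	related	5/10	1	standard	0	TBI/Cy	Tacro/MMF/PTCy	60
UPN08	1	0	C2	related	5/10	1	standard	1	TBI/Cy	Tacro/MMF/PTCy	60
UPN09	1	0	C2	unrelated	10/10	0	high	0	Thiotepa/TBI/Cy	Tacro/Mtx	100
UPN10	1	0	C2	unrelated	10/10	0	standard	1	TBI/Cy	Tacro/MMF	100
UPN11	0	1	C3	related	10/10	0	high	1	TBI/Cy	Mtx	100
UPN12	0	0	C3	related	5/10	0	high	1	TBI/Cy	Tacro/MMF	100
UPN13	0	0	C3	related	5/10	1	high	1	TBI/Cy	Tacro/MMF/PTCy	100
UPN14	0	0	C3	related	5/10	1	standard	1	TBI/Cy	Tacro/MMF/PTCy	100
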