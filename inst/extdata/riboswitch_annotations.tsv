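# Annotation list for the synthetic 52-nt riboswitch-like fold.
# pair  res_i  res_j  class   /   stack  res_i  res_j
pair	3	13	cWW
pair	4	14	cWW
pair	5	15	cWW
pair	6	16	cWW
pair	7	17	cWW
pair	8	18	cWW
pair	16	26	cWW
pair	17	27	cWW
pair	18	28	cWW
pair	19	29	cWW
pair	20	30	cWW
pair	28	38	cWW
pair	29	39	cWW
pair	30	40	cWW
pair	31	41	cWW
pair	32	42	cWW
stack	1	2
stack	2	3
stack	3	4
stack	4	5
stack	5	6
stack	6	7
stack	7	8
stack	8	9
stack	9	10
stack	10	11
stack	11	12
stack	12	13
stack	13	14
stack	14	15
stack	15	16
stack	16	17
stack	17	18
stack	18	19
stack	19	20
stack	20	21
stack	21	22
stack	22	23
stack	23	24
stack	24	25
stack	25	26
stack	26	27
stack	27	28
stack	28	29
stack	29	30
stack	30	31
stack	31	32
stack	32	33
stack	33	34
stack	34	35
stack	35	36
stack	36	37
stack	37	38
stack	38	39
stack	39	40
stack	40	41
stack	41	42
stack	42	43
stack	43	44
stack	44	45
stack	45	46
stack	46	47
stack	47	48
stack	48	49
stack	49	50
stack	50	51
stack	51	52
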