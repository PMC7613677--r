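tag	doc
DIM_COIL	Individual (uncombined) receive-coil elements
DIM_DYN	Repeated measurements / temporal averages
DIM_INDIRECT	Indirect frequency dimension (e.g. 2D NMR)
DIM_EDIT	Spectral-editing conditions
DIM_ISIS	ISIS localization add/subtract acquisitions
DIM_PHASE_CYCLE	Phase-cycling steps
DIM_MEAS	Repetitions of the whole measurement
DIM_USER_0	User-defined purpose 0 (describe in dim_{n}_info)
DIM_USER_1	User-defined purpose 1 (describe in dim_{n}_info)
DIM_USER_2	User-defined purpose 2 (describe in dim_{n}_info)
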