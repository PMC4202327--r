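gene_id	compartments	study_id	condition	evidence
At3g49560	cp	study_TIM	standard	GFP
At5g24650	mt; cp	study_TIM	standard	GFP
At2g23800	ER	study_GGPS	standard	GFP
At4g36810	cp	study_GGPS	standard	GFP
At1g14450	ER	study_NADH	standard	GFP
At2g02510	mt; per; cp	study_NADH	standard	GFP
At1g17050	cp	study_SPS	standard	GFP
At1g78510	ER	study_SPS	standard	GFP
At1g02510	pm	study_TPK	standard	GFP
At4g01840	va	study_TPK	standard	GFP
At3g05790	mt; cp	study_LON	standard	GFP
At5g26860	mt	study_LON	standard	GFP
At1g55920	cp	study_SAT	standard	GFP
At3g13110	mt	study_SAT	standard	GFP
At3g01330	cy; nu	study_DEL	standard	GFP
At5g14960	nu	study_DEL	standard	GFP
At1g13270	cp	study_MAP	standard	GFP
At3g25740	mt; cp	study_MAP	standard	GFP
At1g13460	per	study_PP2A	standard	GFP
At3g26020	nu; cy	study_PP2A	standard	GFP
At3g50990	cw	study_PRX	standard	GFP
At5g66390	cy	study_PRX	standard	GFP
At5g04870	per; lb	study_CPK	standard	GFP
At3g10660	ER	study_CPK	standard	GFP
At2g39800	cyb	study_P5CS	standard	GFP
At3g55610	cy	study_P5CS	standard	GFP
At3g10550	cyb	study_MTM	standard	GFP
At5g04540	cy	study_MTM	standard	GFP
At1g31630	cy	study_AGL	standard	GFP
At1g31640	nu	study_AGL	standard	GFP
At2g33110	ER	study_VAMP	standard	GFP
At2g33120	pm; en	study_VAMP	standard	GFP
At3g08720	nu	study_S6K	standard	GFP
At3g08730	cy	study_S6K	standard	GFP
At5g39510	TGN/PVC	study_VTI	standard	GFP
At5g39630	ER	study_VTI	standard	GFP
At4g15415	nu; cy	study_PP2Ab	standard	GFP
At3g21650	mt; cy	study_PP2Ab	standard	GFP
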