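pair_id	gene1	gene2	duplication_type
TIM_TICM	At3g49560	At5g24650	alpha-WGD
GGPS2_GGPS1	At2g23800	At4g36810	alpha-WGD
NADH_NADH	At1g14450	At2g02510	alpha-WGD
SPS2_SPS1	At1g17050	At1g78510	alpha-WGD
TPK4_TPK5	At1g02510	At4g01840	alpha-WGD
LON4_LON1	At3g05790	At5g26860	alpha-WGD
SAT1_SAT3	At1g55920	At3g13110	alpha-WGD
DEL3_DEL2	At3g01330	At5g14960	alpha-WGD
MAP1C_MAP1B	At1g13270	At3g25740	alpha-WGD
PP2ABtheta_PP2ABeta	At1g13460	At3g26020	alpha-WGD
PRX36_PRX72	At3g50990	At5g66390	alpha-WGD
CPK1_CPK2	At5g04870	At3g10660	alpha-WGD
P5CS1_P5CS2	At2g39800	At3g55610	alpha-WGD
MTM1_MTM2	At3g10550	At5g04540	alpha-WGD
AGL86_AGL92	At1g31630	At1g31640	tandem
VAMP723_VAMP722	At2g33110	At2g33120	tandem
S6K2_S6K1	At3g08720	At3g08730	tandem
VTI11_VTI14	At5g39510	At5g39630	tandem
PP2ABgamma_PP2ABzeta	At4g15415	At3g21650	other
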