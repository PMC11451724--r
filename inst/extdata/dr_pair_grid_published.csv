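lab,cohort,genotype,sex,p_value,direction
Hoffman,1,Canton-S,F,0.07,none
Hoffman,1,Canton-S,M,0.02,none
Hoffman,1,Oregon-R,F,1e-5,DR
Hoffman,1,Oregon-R,M,9e-8,DR
Hoffman,1,w1118,F,1,none
Hoffman,1,w1118,M,5e-9,DR
Hoffman,1,wDahomey,F,1,none
Hoffman,1,wDahomey,M,0.008,none
Hoffman,2,Canton-S,F,3e-5,AL
Hoffman,2,Canton-S,M,0.5,none
Hoffman,2,Oregon-R,F,0.07,none
Hoffman,2,Oregon-R,M,0.001,none
Hoffman,2,w1118,F,0.1,none
Hoffman,2,w1118,M,0.03,none
Hoffman,2,wDahomey,F,0.1,none
Hoffman,2,wDahomey,M,0.01,none
Hoffman,3,Canton-S,F,6e-10,AL
Hoffman,3,Canton-S,M,2e-9,DR
Hoffman,3,Oregon-R,F,0.003,none
Hoffman,3,Oregon-R,M,3e-14,DR
Hoffman,3,w1118,F,0.7,none
Hoffman,3,w1118,M,0.005,none
Hoffman,3,wDahomey,F,1e-4,DR
Hoffman,3,wDahomey,M,0.2,none
Hoffman,4,Canton-S,F,0.1,none
Hoffman,4,Canton-S,M,0.06,none
Hoffman,4,Oregon-R,F,0.8,none
Hoffman,4,Oregon-R,M,3e-10,DR
Hoffman,4,w1118,F,0.5,none
Hoffman,4,w1118,M,3e-7,AL
Hoffman,4,wDahomey,F,0.3,none
Hoffman,4,wDahomey,M,0.3,none
Lyu,1,Canton-S,F,0.4,none
Lyu,1,Canton-S,M,0.1,none
Lyu,1,Oregon-R,F,0.004,none
Lyu,1,Oregon-R,M,0.7,none
Lyu,1,w1118,F,0.2,none
Lyu,1,w1118,M,0.5,none
Lyu,1,wDahomey,F,1e-8,AL
Lyu,1,wDahomey,M,0.8,none
Lyu,2,Canton-S,F,8e-15,DR
Lyu,2,Canton-S,M,5e-17,DR
Lyu,2,Oregon-R,F,0.03,none
Lyu,2,Oregon-R,M,5e-7,DR
Lyu,2,w1118,F,2e-9,DR
Lyu,2,w1118,M,1e-7,DR
Lyu,2,wDahomey,F,0.04,none
Lyu,2,wDahomey,M,0.6,none
Lyu,3,Canton-S,F,0.02,none
Lyu,3,Canton-S,M,0.004,none
Lyu,3,Oregon-R,F,0.01,none
Lyu,3,Oregon-R,M,0.06,none
Lyu,3,w1118,F,0.008,none
Lyu,3,w1118,M,5e-4,DR
Lyu,3,wDahomey,F,0.1,none
Lyu,3,wDahomey,M,0.8,none
Lyu,4,Canton-S,F,6e-6,AL
Lyu,4,Canton-S,M,7e-4,DR
Lyu,4,Oregon-R,F,6e-5,DR
Lyu,4,Oregon-R,M,3e-6,DR
Lyu,4,w1118,F,0.8,none
Lyu,4,w1118,M,2e-4,DR
Lyu,4,wDahomey,F,0.6,none
Lyu,4,wDahomey,M,0.06,none
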