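item,label,bias,factor1,factor2
1,sleep_hours,0.0689,0.1525,0.0041
2,sleep_quality,0.0390,0.2089,0.0040
3,appetite,0.0446,0.1980,0.0009
4,medication_taken,0.0795,0.0566,0.0225
5,mood_joyful,0.0133,0.3228,0.0006
6,calm_relaxed,0.0223,0.3181,0.0012
7,active_energetic,0.0130,0.3811,0.0103
8,awake_rested,0.0496,0.3894,0.0041
9,daily_life_interest,0.0199,0.4236,0.0000
10,concentration,0.0276,0.3467,0.0013
11,useful_role,0.0187,0.3756,0.0018
12,decision_making,0.0173,0.3529,0.0002
13,enjoy_activities,0.0100,0.3739,0.0016
14,coping,0.0149,0.3674,0.0016
15,reasonably_happy,0.0174,0.3591,0.0030
16,aggressiveness,0.1745,0.0053,0.2362
17,suicidal_thoughts,0.3177,0.0012,0.4573
18,worry_sleep_loss,0.0422,0.0210,0.2931
19,overwhelmed_tense,0.0109,0.0006,0.3108
20,cannot_overcome,0.0060,0.0015,0.3005
21,unhappy_depressed,0.0001,0.0037,0.4213
22,lost_confidence,0.0083,0.0071,0.4784
23,worthlessness,0.1097,0.0010,0.6198
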