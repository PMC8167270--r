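item_id,attribute,rater_id,value
item_1,health_relevance,rater_1,A
item_1,health_relevance,rater_2,A
item_2,health_relevance,rater_1,A
item_2,health_relevance,rater_2,A
item_3,health_relevance,rater_1,C
item_3,health_relevance,rater_2,C
item_4,health_relevance,rater_1,A
item_4,health_relevance,rater_2,A
item_5,health_relevance,rater_1,A
item_5,health_relevance,rater_2,A
item_6,health_relevance,rater_1,D
item_6,health_relevance,rater_2,D
item_7,health_relevance,rater_1,A
item_7,health_relevance,rater_2,A
item_8,health_relevance,rater_1,A
item_8,health_relevance,rater_2,A
item_9,health_relevance,rater_1,B
item_9,health_relevance,rater_2,B
item_10,health_relevance,rater_1,A
item_10,health_relevance,rater_2,A
item_11,health_relevance,rater_1,A
item_11,health_relevance,rater_2,A
item_12,health_relevance,rater_1,A
item_12,health_relevance,rater_2,A
item_13,health_relevance,rater_1,D
item_13,health_relevance,rater_2,D
item_14,health_relevance,rater_1,B
item_14,health_relevance,rater_2,B
item_15,health_relevance,rater_1,B
item_15,health_relevance,rater_2,B
item_16,health_relevance,rater_1,C
item_16,health_relevance,rater_2,C
item_17,health_relevance,rater_1,A
item_17,health_relevance,rater_2,A
item_18,health_relevance,rater_1,A
item_18,health_relevance,rater_2,A
item_19,health_relevance,rater_1,A
item_19,health_relevance,rater_2,A
item_20,health_relevance,rater_1,A
item_20,health_relevance,rater_2,A
item_21,health_relevance,rater_1,A
item_21,health_relevance,rater_2,B
item_22,health_relevance,rater_1,C
item_22,health_relevance,rater_2,C
item_23,health_relevance,rater_1,A
item_23,health_relevance,rater_2,A
item_24,health_relevance,rater_1,A
item_24,health_relevance,rater_2,A
item_25,health_relevance,rater_1,A
item_25,health_relevance,rater_2,A
item_1,elsis,rater_1,C
item_1,elsis,rater_2,C
item_2,elsis,rater_1,B
item_2,elsis,rater_2,B
item_3,elsis,rater_1,D
item_3,elsis,rater_2,D
item_4,elsis,rater_1,C
item_4,elsis,rater_2,C
item_5,elsis,rater_1,C
item_5,elsis,rater_2,C
item_6,elsis,rater_1,C
item_6,elsis,rater_2,C
item_7,elsis,rater_1,C
item_7,elsis,rater_2,D
item_8,elsis,rater_1,C
item_8,elsis,rater_2,B
item_9,elsis,rater_1,C
item_9,elsis,rater_2,B
item_10,elsis,rater_1,C
item_10,elsis,rater_2,C
item_11,elsis,rater_1,C
item_11,elsis,rater_2,D
item_12,elsis,rater_1,B
item_12,elsis,rater_2,B
item_13,elsis,rater_1,C
item_13,elsis,rater_2,B
item_14,elsis,rater_1,C
item_14,elsis,rater_2,C
item_15,elsis,rater_1,C
item_15,elsis,rater_2,C
item_16,elsis,rater_1,C
item_16,elsis,rater_2,C
item_17,elsis,rater_1,C
item_17,elsis,rater_2,C
item_18,elsis,rater_1,C
item_18,elsis,rater_2,B
item_19,elsis,rater_1,B
item_19,elsis,rater_2,B
item_20,elsis,rater_1,C
item_20,elsis,rater_2,B
item_21,elsis,rater_1,C
item_21,elsis,rater_2,C
item_22,elsis,rater_1,B
item_22,elsis,rater_2,B
item_23,elsis,rater_1,C
item_23,elsis,rater_2,C
item_24,elsis,rater_1,B
item_24,elsis,rater_2,B
item_25,elsis,rater_1,C
item_25,elsis,rater_2,C
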