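region,contribution,sign
hallux,6.41,-
toes_2_5,5.78,-
metatarsal_1,9.44,-
metatarsal_2,9.17,+
metatarsal_3,13.58,+
metatarsal_4,14.71,+
metatarsal_5,8.15,+
midfoot,12.43,-
medial_heel,12.58,+
lateral_heel,7.75,+
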