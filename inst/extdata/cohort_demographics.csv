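no,sex,breed,age_years,bcs,height_cm,lameness,background,current_training
1,G,PHB,15,3,166,0,leisure work for 10 years,"1-2 h/day, 5 days/week"
2,G,PHB,17,4,155,0,leisure work for 13 years,"1-2 h/day, 5 days/week"
3,M,MLP,18,3,167,0,leisure work for 14 years,"1-2 h/day, 5 days/week"
4,M,PHB,10,3,168,0,leisure work for 5 years,"1-2 h/day, 5 days/week"
5,G,MLP,8,4,164,0,leisure work for 4 years,"1-2 h/day, 5 days/week"
6,G,MLP,12,3,166,0,leisure work for 8 years,"1-2 h/day, 5 days/week"
7,M,MLP,16,3,154,0,leisure work for 11 years,"1-2 h/day, 5 days/week"
8,G,PHB,14,4,160,0,leisure work for 9 years,"1-2 h/day, 5 days/week"
9,M,MLP,10,3,161,0,leisure work for 8 years,"1-2 h/day, 5 days/week"
10,G,PHB,18,3,159,0,leisure work for 14 years,"1-2 h/day, 5 days/week"
11,G,PHB,6,4,152,0,leisure work for 2 years,"1-2 h/day, 5 days/week"
12,M,PHB,12,3,160,0,leisure work for 8 years,"1-2 h/day, 5 days/week"
13,G,PHB,8,3,156,0,leisure work for 2 years,"1-2 h/day, 5 days/week"
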