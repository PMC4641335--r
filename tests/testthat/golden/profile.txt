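SeMaS profile  respondent: T1
construct            score  category     low -------------- high
burden              8.6/10  minor        [-----..........--X---]
self_efficacy          2/6  minor        [=====--X----.........]
locus                   +3  none (internal) [....................X]
anxiety               0/16  none         [X....-----===========]
depression            0/12  none         [X....-----===========]
coping                 6/6  minor (P+E)  [....................X]
social_support       10/12  none         [===--............X...]
guidance  computer_skills: 2  group_functioning: 2  self_monitoring_willingness: 2
barriers: 3  not scorable: 0
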