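# Default point scheme: own-group thresholds at 6 (5 points) and 9
# (a further 7), plus 4 points for each other group reaching 9.
own_small_threshold: 6
own_small_points: 5
own_large_threshold: 9
own_large_points: 7
other_large_threshold: 9
other_large_points: 4
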