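family	state	lml
torricelli	anchor 2 (proper)	-39.45
torricelli	anchor 2 (non-proper)	-40.55
torricelli	anchor 5	-40.46
ntng	anchor 2	-86.44
ntng	anchor 5	-88.18
ntng	anchor 10	-87.72
ntng	anchor 4	-88.67
ramu	anchor 2 (proper)	-20.39
ramu	anchor 2 (non-proper)	-21.21
ramu	anchor 5	-22.03
sepik	anchor 2 (proper)	-24.41
sepik	anchor 2 (non-proper)	-24.51
sepik	anchor 5	-24.29
papuanall	anchor 2 (proper)	-525.6
papuanall	anchor 2 (non-proper)	-527.67
papuanall	anchor 5	-526.41
papuanall	anchor 10	-526.9
papuanall	anchor 4	-525.9
papuanall	anchor 6	-528.9
papuanbig4	anchor 2 (proper)	-274.2
papuanbig4	anchor 2 (non-proper)	-275.92
papuanbig4	anchor 5	-275.27
papuanbig4	anchor 10	-276.09
papuanbig4	anchor 4	-275.1
arawakan	restricted	-60.11
arawakan	anchor 2	-58.37
arawakan	anchor 5	-59.34
arawakan	anchor 10	-58.42
panotacanan	restricted	-29.81
panotacanan	anchor 2	-29.73
panotacanan	anchor 5	-29.78
tucanoan	restricted	-9.52
tucanoan	anchor 2	-9.72
tucanoan	anchor 5	-8.43
tucanoan	anchor 20	-9.82
tupian	restricted	-52.52
tupian	anchor 2	-55.57
tupian	anchor 5	-54.43
tupian	anchor 10	-56.17
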