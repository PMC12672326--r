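strategy,total_cost,total_qaly
Statins alone,13706.18,12.32
Evolocumab 140 mg Q2W,24815.45,12.74
Alirocumab 75 mg Q2W,24946.32,12.64
Tafolecimab 150 mg Q2W,25767.16,12.67
Tafolecimab 600 mg Q6W,29879.66,12.66
Evolocumab 420 mg Q4W,30934.51,12.70
Tafolecimab 450 mg Q4W,31117.00,12.71
Alirocumab 150 mg Q2W,37624.59,12.67
Alirocumab 300 mg Q4W,37679.37,12.68
Inclisiran 300 mg Q6M,48693.34,12.62
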