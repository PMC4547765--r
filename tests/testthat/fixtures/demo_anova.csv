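effect,ss,df,ms,statistic,p.value
group,0.025787457418791022,1,0.025787457418791022,2.7792832764834383,0.12645608616603896
subject_within_group,0.0927845593753915,10,0.00927845593753915,NA,NA
time,0.15022142656370596,4,0.03755535664092649,17.18011796598896,2.8173520464799838e-8
group_x_time,0.08419652902063823,4,0.02104913225515956,9.629160992476281,1.499112554095386e-5
residual,0.08743911238624524,40,0.002185977809656131,NA,NA
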