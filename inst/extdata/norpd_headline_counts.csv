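measure,year,washout_months,count,mean_population,printed_percent
prevalent_any,2011,24,156540,4953217,3.2
prevalent_insulin_only,2010,24,31515,4888946,0.64
prevalent_insulin_only,2010,72,27927,4888946,0.57
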